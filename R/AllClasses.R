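#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

#' TranscriptSet: exon-structured transcript models
#'
#' A container for transcript models, the unit of lncRNA discovery and
#' positional classification.  Each transcript is an ordered set of exons on
#' one chromosome and strand, held as one element of a
#' \linkS4class{GRangesList} named by transcript id, together with a
#' per-transcript table carrying the parent gene id and the annotation
#' category (\code{known_coding}, \code{known_lncRNA} or \code{assembled}).
#'
#' Invariants enforced by the validity method: exons of a transcript are
#' sorted by start, pairwise non-overlapping, and all on the same chromosome
#' and strand (\code{+} or \code{-}); every transcript has at least one exon;
#' transcript ids are unique and match the rows of the transcript table.
#'
#' @slot exons A \code{GRangesList}, one element per transcript, named by
#'   transcript id.
#' @slot txData A \code{DataFrame} with one row per transcript (rownames are
#'   transcript ids) and columns \code{gene_id} and \code{category}.
#'
#' @seealso [readAnnotation()], [makeTranscriptSet()], [txSpans()]
#' @export
setClass("TranscriptSet",
  slots = c(exons = "GRangesList", txData = "DataFrame")
)

.TX_CATEGORIES <- c("known_coding", "known_lncRNA", "assembled")

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  msgs <- character()
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    msgs <- c(msgs, "transcript ids (names of 'exons') must be unique and non-NULL")
  if (!identical(rownames(td), names(ex)))
    msgs <- c(msgs, "rownames of 'txData' must equal names of 'exons'")
  if (!all(c("gene_id", "category") %in% colnames(td)))
    msgs <- c(msgs, "'txData' must have columns 'gene_id' and 'category'")
  else if (!all(td$category %in% .TX_CATEGORIES))
    msgs <- c(msgs, sprintf("category must be one of: %s",
                            paste(.TX_CATEGORIES, collapse = ", ")))
  if (length(ex)) {
    n_ex <- S4Vectors::elementNROWS(ex)
    if (any(n_ex == 0L))
      msgs <- c(msgs, "every transcript must have at least one exon")
    flat <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(ex), n_ex)
    if (any(tapply(as.character(seqnames(flat)), grp,
                   function(x) length(unique(x))) > 1L))
      msgs <- c(msgs, "all exons of a transcript must share one chromosome")
    str_ok <- tapply(as.character(strand(flat)), grp, function(x) {
      length(unique(x)) == 1L && x[1] %in% c("+", "-")
    })
    if (!all(str_ok))
      msgs <- c(msgs, "all exons of a transcript must share one strand, '+' or '-'")
    # sorted by start and pairwise non-overlapping within each transcript
    st <- start(flat); en <- end(flat)
    prev_same <- c(FALSE, grp[-1] == grp[-length(grp)])
    if (any(prev_same & st <= c(0L, en[-length(en)])))
      msgs <- c(msgs, "exons must be sorted by start and pairwise non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons A named \code{GRangesList} of exons, one element per
#'   transcript.  Exons are sorted by start position on construction.
#' @param geneId Character vector of parent gene ids, one per transcript.
#' @param category Character vector (recycled if length 1) of annotation
#'   categories, each one of \code{"known_coding"}, \code{"known_lncRNA"},
#'   \code{"assembled"}.
#' @return A \linkS4class{TranscriptSet}.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 500)), "+"))
#' ts <- TranscriptSet(ex, geneId = "g1", category = "assembled")
#' txLengths(ts)
#' @export
TranscriptSet <- function(exons, geneId, category = "assembled") {
  if (!is(exons, "GRangesList")) exons <- GRangesList(exons)
  # sort exons by start within each transcript on the flat representation
  flat <- unlist(exons, use.names = FALSE)
  grp <- rep(seq_along(exons), S4Vectors::elementNROWS(exons))
  o <- order(grp, start(flat))
  exons <- IRanges::relist(flat[o], exons)
  mcols(exons@unlistData) <- NULL
  n <- length(exons)
  category <- rep_len(category, n)
  geneId <- rep_len(geneId, n)
  td <- DataFrame(gene_id = as.character(geneId),
                  category = as.character(category),
                  row.names = names(exons))
  new("TranscriptSet", exons = exons, txData = td)
}

#' Build a TranscriptSet from a flat exon table
#'
#' Convenience constructor from one row per exon.
#'
#' @param df A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based, closed), \code{strand}, \code{transcript_id}, \code{gene_id},
#'   and optionally \code{category}.
#' @return A \linkS4class{TranscriptSet}.
#' @export
makeTranscriptSet <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand",
                  "transcript_id", "gene_id") %in% names(df)))
  if (any(df$end < df$start))
    stop("exon with end < start: validation error")
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  ex <- S4Vectors::split(gr, factor(df$transcript_id, unique(df$transcript_id)))
  first <- !duplicated(df$transcript_id)
  cat <- if ("category" %in% names(df)) df$category[first] else "assembled"
  TranscriptSet(ex, geneId = df$gene_id[first], category = cat)
}

setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("names", "TranscriptSet", function(x) names(x@exons))

setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  initialize(x, exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

setMethod("show", "TranscriptSet", function(object) {
  cat(sprintf("TranscriptSet with %d transcripts\n", length(object)))
  tab <- table(object@txData$category)
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (length(object)) {
    sp <- txSpans(object)
    cat("  chromosomes:",
        paste(unique(as.character(seqnames(sp))), collapse = ", "), "\n")
  }
})
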