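#' Read transcript models from GTF/GFF3
#'
#' Imports transcript/exon records into a \linkS4class{TranscriptSet}.
#' Every exon is attached to its transcript; exons are sorted by start.
#' Chromosome names are taken verbatim (no reference check).  The
#' annotation category of each transcript (\code{known_coding},
#' \code{known_lncRNA} or \code{assembled}) is read from a configurable
#' attribute key; transcripts without that attribute are treated as
#' \code{assembled}.
#'
#' @param path Path to a GTF (2.2) or GFF3 file with transcript/exon rows.
#'   Format is inferred from the file extension.
#' @param categoryKey Attribute key holding the annotation category.
#' @return A \linkS4class{TranscriptSet}.
#' @seealso [writeAnnotation()] for the inverse; the pair round-trips all
#'   models field-for-field.
#' @export
readAnnotation <- function(path, categoryKey = "category") {
  gr <- rtracklayer::import(path)
  m <- mcols(gr)
  ex <- gr[!is.na(m$type) & tolower(as.character(m$type)) == "exon"]
  if (!length(ex)) stop("no exon records found in ", path)
  em <- mcols(ex)
  tx_id <- if (!is.null(em$transcript_id)) {
    as.character(em$transcript_id)
  } else if (!is.null(em$Parent)) {
    as.character(unlist(em$Parent))        # GFF3: exon Parent is transcript
  } else stop("exon records carry neither 'transcript_id' nor 'Parent'")
  if (anyNA(tx_id)) stop("exon record without transcript id")
  first <- !duplicated(tx_id)
  gene_id <- if (!is.null(em$gene_id)) {
    as.character(em$gene_id)[first]
  } else {
    # GFF3: look the parent gene up from the transcript-level records
    tx_rec <- gr[!is.na(m$ID) & m$ID %in% tx_id]
    par <- vapply(as.list(mcols(tx_rec)$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    map <- stats::setNames(par, mcols(tx_rec)$ID)
    unname(map[tx_id[first]])
  }
  gene_id[is.na(gene_id)] <- tx_id[first][is.na(gene_id)]
  cat_col <- em[[categoryKey]]
  category <- if (!is.null(cat_col)) as.character(cat_col)[first] else NA_character_
  if (is.null(cat_col) || anyNA(category)) {
    # fall back to transcript-level records for the category attribute
    tx_rec_cat <- mcols(gr)[[categoryKey]]
    if (!is.null(tx_rec_cat) && !is.null(m$transcript_id)) {
      map <- stats::setNames(as.character(tx_rec_cat), as.character(m$transcript_id))
      map <- map[!is.na(map) & !is.na(names(map))]
      miss <- is.na(category)
      if (is.null(cat_col)) category <- rep(NA_character_, sum(first))
      category[miss] <- unname(map[tx_id[first][miss]])
    }
  }
  category[is.na(category)] <- "assembled"
  mcols(ex) <- NULL
  exl <- S4Vectors::split(ex, factor(tx_id, tx_id[first]))
  TranscriptSet(exl, geneId = gene_id, category = category)
}

#' Write transcript models to GTF
#'
#' Writes one \code{transcript} row and one \code{exon} row per exon, with
#' \code{transcript_id}, \code{gene_id} and the annotation category as
#' attributes.  \code{readAnnotation(writeAnnotation(x))} reproduces
#' \code{x} field-for-field.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @param path Output GTF path.
#' @param categoryKey Attribute key used for the category.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(x, path, categoryKey = "category") {
  stopifnot(is(x, "TranscriptSet"))
  n_ex <- S4Vectors::elementNROWS(x@exons)
  flat <- unlist(x@exons, use.names = FALSE)
  tx_id <- rep(names(x@exons), n_ex)
  gene <- rep(x@txData$gene_id, n_ex)
  cat_ <- rep(x@txData$category, n_ex)

  tx_rows <- txSpans(x)
  mcols(tx_rows) <- NULL
  all_gr <- c(tx_rows, flat)
  md <- DataFrame(
    source = "lncflow",
    type = c(rep("transcript", length(tx_rows)), rep("exon", length(flat))),
    transcript_id = c(names(x@exons), tx_id),
    gene_id = c(x@txData$gene_id, gene))
  md[[categoryKey]] <- c(x@txData$category, cat_)
  mcols(all_gr) <- md
  names(all_gr) <- NULL
  # group rows per transcript so the file reads naturally
  all_gr <- all_gr[order(match(mcols(all_gr)$transcript_id, names(x@exons)),
                         mcols(all_gr)$type != "transcript",
                         start(all_gr))]
  rtracklayer::export(all_gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' Sequence ids are truncated at the first whitespace so that they match
#' transcript ids.
#'
#' @param path FASTA file of transcript (spliced, sense-strand) sequences.
#' @return A \code{DNAStringSet} named by transcript id.
#' @export
readTranscriptSequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
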