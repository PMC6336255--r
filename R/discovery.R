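#' Collapse transcripts with identical exon structure
#'
#' Transcripts sharing chromosome, strand, and the exact exon coordinate
#' set collapse to a single record; the first id (in input order) survives.
#' Models differing by a single base in any exon are kept apart.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return A \linkS4class{TranscriptSet} with duplicates removed.
#' @export
deduplicateTranscripts <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  if (!length(x)) return(x)
  flat <- unlist(x@exons, use.names = FALSE)
  grp <- rep(seq_along(x@exons), S4Vectors::elementNROWS(x@exons))
  coord <- paste0(start(flat), "-", end(flat))
  key <- paste(
    vapply(split(coord, grp), paste, character(1), collapse = ","),
    as.character(seqnames(flat))[!duplicated(grp)],
    as.character(strand(flat))[!duplicated(grp)], sep = "|")
  x[!duplicated(key)]
}

.FILTER_STEPS <- c("length", "coverage", "known_overlap",
                   "known_lnc_similarity", "coding_potential")

#' Novel-lncRNA filter cascade
#'
#' Applies the stepwise novelty screen to assembled transcripts, in fixed
#' cascade order:
#' \enumerate{
#'   \item \strong{length} — spliced length >= \code{minLength} bp kept
#'     (transcripts shorter than 200 bp are filtered);
#'   \item \strong{coverage} — read coverage >= \code{minCoverage} kept;
#'   \item \strong{known_overlap} — transcripts flagged as overlapping a
#'     known coding gene removed; then \strong{known_lnc_similarity} —
#'     identity to a known lncRNA > \code{maxKnownIdentity}\% removed;
#'   \item \strong{coding_potential} — kept only if the coding-potential
#'     score is < \code{cpcCutoff} \emph{and} there is no protein-domain
#'     (Pfam) hit.
#' }
#' Survivors are the novel lncRNA set.  \code{failed_step} records the
#' \emph{first} violated step, so a decoy violating exactly one step is
#' attributed to it exactly.  Boundary semantics follow the printed
#' inequalities literally: length exactly 200 and coverage exactly 3 are
#' kept, identity exactly 90\% is kept, a coding-potential score of exactly
#' 0 is removed.
#'
#' Coding evidence (coding-potential score, domain hits, coverage, identity)
#' is consumed as a table computed by external scorers; only the decision
#' logic lives here.
#'
#' @param transcripts A \linkS4class{TranscriptSet} of assembled
#'   (deduplicated) transcripts.
#' @param evidence A data.frame with one row per assembled transcript and
#'   columns \code{transcript_id}, \code{cpc_score}, \code{pfam_hit}
#'   (logical or 0/1), \code{read_coverage}, \code{known_lnc_identity}
#'   (percent, \code{NA} allowed), \code{overlaps_known_coding} (logical or
#'   0/1).
#' @param minLength,minCoverage,maxKnownIdentity,cpcCutoff Thresholds;
#'   defaults are the standard screen (200 bp, 3, 90\%, 0).
#' @return A data.frame with columns \code{transcript_id}, \code{passed},
#'   \code{failed_step} (one of \code{length}, \code{coverage},
#'   \code{known_overlap}, \code{known_lnc_similarity},
#'   \code{coding_potential}, \code{none}).  \code{passed} is \code{TRUE}
#'   iff \code{failed_step == "none"}.
#' @export
runFilterCascade <- function(transcripts, evidence,
                             minLength = 200, minCoverage = 3,
                             maxKnownIdentity = 90, cpcCutoff = 0) {
  stopifnot(is(transcripts, "TranscriptSet"))
  req <- c("transcript_id", "cpc_score", "pfam_hit", "read_coverage",
           "known_lnc_identity", "overlaps_known_coding")
  miss <- setdiff(req, names(evidence))
  if (length(miss))
    stop("evidence table lacks columns: ", paste(miss, collapse = ", "))
  ids <- transcriptIds(transcripts)
  idx <- match(ids, evidence$transcript_id)
  if (anyNA(idx))
    stop("missing evidence record for transcript(s): ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  ev <- evidence[idx, ]
  if (any(ev$read_coverage < 0, na.rm = TRUE))
    stop("negative read_coverage: validation error")
  len <- unname(txLengths(transcripts))
  pfam <- as.logical(ev$pfam_hit)
  ovl <- as.logical(ev$overlaps_known_coding)
  ident <- ev$known_lnc_identity
  if (any(ident < 0 | ident > 100, na.rm = TRUE))
    stop("known_lnc_identity outside [0, 100]")

  failed <- rep("none", length(ids))
  pass_cp <- ev$cpc_score < cpcCutoff & !pfam
  failed[!pass_cp] <- "coding_potential"
  failed[!is.na(ident) & ident > maxKnownIdentity] <- "known_lnc_similarity"
  failed[ovl] <- "known_overlap"
  failed[ev$read_coverage < minCoverage] <- "coverage"
  failed[len < minLength] <- "length"

  data.frame(transcript_id = ids, passed = failed == "none",
             failed_step = failed, row.names = NULL)
}

.ORF_STOPS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame on the sense strand
#'
#' Length in bp (including the stop codon) of the longest ATG-initiated,
#' in-frame stop-terminated ORF across the three sense-strand reading
#' frames; 0 when no complete ORF exists.  Transcript sequences from a
#' strand-specific library are already oriented, so the reverse strand is
#' not searched.
#'
#' @param seq A single character string or \code{DNAString} over
#'   \{A, C, G, T, N\}, or a \code{DNAStringSet}/character vector (a length
#'   per element is returned).
#' @return Integer vector of ORF lengths in bp.
#' @examples
#' findLongestOrf("ATGAAATAG")  # 9
#' findLongestOrf("CCCCCC")     # 0
#' @export
findLongestOrf <- function(seq) {
  if (is(seq, "DNAStringSet") || (is.character(seq) && length(seq) > 1))
    return(vapply(as.character(seq), .longestOrf1, integer(1), USE.NAMES = !is.null(names(seq))))
  .longestOrf1(as.character(seq))
}

.longestOrf1 <- function(s) {
  s <- toupper(s)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(s)
  best <- 0L
  for (off in 0:2) {
    n_cod <- (n - off) %/% 3L
    if (n_cod < 2L) next
    codons <- substring(s, off + 3L * (seq_len(n_cod) - 1L) + 1L,
                        off + 3L * seq_len(n_cod))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% .ORF_STOPS)
    if (!length(starts) || !length(stops)) next
    # first stop at or after each start codon
    j <- findInterval(starts - 1L, stops) + 1L
    ok <- j <= length(stops)
    if (!any(ok)) next
    best <- max(best, 3L * (stops[j[ok]] - starts[ok] + 1L))
  }
  best
}

#' Per-transcript characterization table
#'
#' One row per transcript with spliced length, exon count and (when
#' sequences are supplied) longest-ORF length — the inputs for
#' length/exon/ORF histograms.  Binning is left to the caller.
#'
#' @param transcripts A \linkS4class{TranscriptSet}.
#' @param sequences Optional \code{DNAStringSet} named by transcript id.
#' @return A data.frame with columns \code{transcript_id}, \code{length},
#'   \code{n_exons}, \code{orf_length} (\code{NA} without sequences),
#'   \code{category}.
#' @export
characterizeTranscripts <- function(transcripts, sequences = NULL) {
  stopifnot(is(transcripts, "TranscriptSet"))
  ids <- transcriptIds(transcripts)
  out <- data.frame(
    transcript_id = ids,
    length = unname(txLengths(transcripts)),
    n_exons = unname(S4Vectors::elementNROWS(txExons(transcripts))),
    orf_length = NA_integer_,
    category = unname(txCategory(transcripts)),
    row.names = NULL)
  if (!is.null(sequences)) {
    idx <- match(ids, names(sequences))
    hit <- !is.na(idx)
    out$orf_length[hit] <- unname(findLongestOrf(sequences[idx[hit]]))
  }
  out
}
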