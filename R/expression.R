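#' Assemble a counts SummarizedExperiment
#'
#' Wraps a raw count matrix with its tissue/replicate design.  Sample
#' (column) names follow the \code{tissue_replicate} convention
#' (e.g. \code{flower_1}); tissue and replicate are parsed from them when
#' not given explicitly.
#'
#' @param counts Numeric matrix, features x samples, non-negative.
#' @param tissue,replicate Optional character/integer vectors per sample;
#'   parsed from \code{colnames(counts)} when \code{NULL}.
#' @return A \code{SummarizedExperiment} with assay \code{"counts"} and
#'   colData columns \code{tissue}, \code{replicate}.
#' @export
makeExpressionSE <- function(counts, tissue = NULL, replicate = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(tissue)) {
    if (is.null(colnames(counts))) stop("need colnames or explicit tissue labels")
    tissue <- sub("_[^_]+$", "", colnames(counts))
  }
  if (is.null(replicate))
    replicate <- as.integer(sub("^.*_", "", colnames(counts)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(tissue = tissue, replicate = replicate,
                        row.names = colnames(counts)))
}

#' RPKM from raw counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{RPKM = 10^9 C / (N L)}
#' where \eqn{C} is the count of reads assigned to the feature in a sample,
#' \eqn{N} the sample's total assigned reads (column sum), and \eqn{L} the
#' feature length in bases.  Zero counts map to zero.
#'
#' @param counts A features-x-samples count matrix, or a
#'   \code{SummarizedExperiment} with a \code{"counts"} assay.
#' @param lengths Per-feature lengths in bp (named, or in row order);
#'   all > 0.
#' @return Same shape as the input: an RPKM matrix, or the
#'   \code{SummarizedExperiment} with an added \code{"rpkm"} assay.
#' @examples
#' m <- matrix(c(100, 9999900), 2, 1,
#'             dimnames = list(c("a", "b"), "flower_1"))
#' computeRpkm(m, c(a = 1000, b = 1000))["a", ]  # 10
#' @export
computeRpkm <- function(counts, lengths) {
  se <- NULL
  if (is(counts, "SummarizedExperiment")) {
    se <- counts
    counts <- SummarizedExperiment::assay(se, "counts")
  }
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    idx <- match(rownames(counts), names(lengths))
    if (anyNA(idx)) stop("lengths missing for some features")
    lengths <- lengths[idx]
  }
  if (length(lengths) != nrow(counts))
    stop("one length per feature required")
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  N <- colSums(counts)
  if (any(N == 0)) stop("zero column sum: RPKM normalization undefined")
  rpkm <- 1e9 * sweep(counts, 1, as.numeric(lengths), "/")
  rpkm <- sweep(rpkm, 2, N, "/")
  if (!is.null(se)) {
    SummarizedExperiment::assays(se)$rpkm <- rpkm
    se
  } else rpkm
}

#' Per-tissue expressed feature sets
#'
#' A feature counts as expressed in a tissue when its replicate-aggregated
#' RPKM reaches \code{threshold} (default 1; features with mean RPKM < 1
#' are treated as low-expression and dropped).  The comparison is
#' inclusive: an aggregate of exactly \code{threshold} is expressed.
#'
#' @param rpkm RPKM matrix (features x samples) or a
#'   \code{SummarizedExperiment} with an \code{"rpkm"} assay and
#'   \code{tissue} colData.
#' @param tissue Character vector of tissue labels per sample (ignored for
#'   a \code{SummarizedExperiment}).
#' @param threshold RPKM cutoff.
#' @param rule Replicate aggregation: \code{"mean"} (default) or
#'   \code{"max"}.
#' @return Named list of character vectors, one expressed-feature set per
#'   tissue.
#' @export
expressedSets <- function(rpkm, tissue = NULL, threshold = 1,
                          rule = c("mean", "max")) {
  rule <- match.arg(rule)
  if (is(rpkm, "SummarizedExperiment")) {
    tissue <- SummarizedExperiment::colData(rpkm)$tissue
    rpkm <- SummarizedExperiment::assay(rpkm, "rpkm")
  }
  if (is.null(tissue)) stop("tissue labels required")
  stopifnot(length(tissue) == ncol(rpkm))
  agg <- if (rule == "mean") rowMeans else function(m) apply(m, 1, max)
  lapply(split(seq_along(tissue), tissue), function(cols) {
    m <- rpkm[, cols, drop = FALSE]
    rownames(rpkm)[agg(m) >= threshold]
  })
}

#' Venn partition of feature sets
#'
#' Partitions the union of 2-4 feature sets into its disjoint Venn regions
#' (7 regions for 3 sets).  Region names join the member set names with
#' \code{&}; single-set regions are the tissue-specific lists.
#'
#' @param sets Named list of 2-4 character vectors.
#' @return A list with \code{counts} (named integer vector over regions)
#'   and \code{members} (named list of feature ids per region).  Regions
#'   are disjoint and their union is the union of the input sets.
#' @examples
#' vennPartition(list(F = c("a", "b"), L = c("b", "c"), R = "b"))$counts
#' @export
vennPartition <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4) stop("need 2-4 sets")
  if (is.null(names(sets))) stop("sets must be named")
  all_ids <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) memb <- matrix(memb, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  names(combos) <- names(sets)
  region_names <- apply(combos, 1, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  members <- lapply(seq_len(nrow(combos)), function(i) {
    r <- as.logical(combos[i, ])
    if (length(all_ids) == 0) return(character())
    sel <- apply(memb, 1, function(m) identical(unname(m), r))
    all_ids[sel]
  })
  names(members) <- region_names
  list(counts = vapply(members, length, integer(1)), members = members)
}
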