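#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector
#' (\eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}, capped at 1), computed
#' through \code{stats::p.adjust} after validating the input.  Adjusted
#' values are monotone non-decreasing in p-rank.
#'
#' @param pvalues Numeric vector with all values in [0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bhAdjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

.DE_STATS <- c("nbz", "poisson")

#' Differential expression screen for one tissue pair
#'
#' Tests each feature for differential expression between two tissues and
#' applies the screening rule: a feature is significant when its fold
#' change is at least \code{fcCutoff} (i.e. |log2 fold change| >=
#' log2(\code{fcCutoff})) \emph{and} its BH-adjusted q-value is at most
#' \code{qCutoff}.  Defaults reproduce the standard screen (fold change
#' >= 2, Q <= 0.01).
#'
#' The fold change is \code{log2((mA + c) / (mB + c))} over the per-group
#' means of library-size-normalized counts, with pseudo-count \code{c} to
#' stabilize zeros.  Two statistics are available:
#' \describe{
#'   \item{\code{nbz}}{(default) Two-sided Wald z-test on the log-ratio of
#'     group means of normalized counts.  The variance uses a
#'     negative-binomial model with a single common dispersion pooled
#'     across all features by moments, so replicate overdispersion is
#'     respected while each feature borrows strength from the whole
#'     matrix; with no overdispersion it reduces to the Poisson z-test.}
#'   \item{\code{poisson}}{Exact conditional binomial test of the pooled
#'     group counts against the library-size split (the exact Poisson
#'     two-sample test).}
#' }
#'
#' @param counts Count matrix (features x samples) or a
#'   \code{SummarizedExperiment} with a \code{"counts"} assay and
#'   \code{tissue} colData.
#' @param contrast Character vector of two tissue names, tested as
#'   first-vs-second; swapping them negates every log2 fold change and
#'   preserves significance.
#' @param tissue Tissue label per sample (ignored for a
#'   \code{SummarizedExperiment}).
#' @param stat Test statistic, one of \code{"nbz"}, \code{"poisson"}.
#' @param fcCutoff,qCutoff Screen thresholds (fold change, BH q).
#' @param pseudoCount Pseudo-count \code{c} in normalized units.
#' @return A data.frame with columns \code{feature_id}, \code{contrast},
#'   \code{log2fc}, \code{pvalue}, \code{qvalue}, \code{direction}
#'   (\code{up}/\code{down}/\code{none}), \code{significant}.
#' @export
deTest <- function(counts, contrast, tissue = NULL, stat = "nbz",
                   fcCutoff = 2, qCutoff = 0.01, pseudoCount = 1) {
  if (!stat %in% .DE_STATS)
    stop("unknown statistic '", stat, "'; available: ",
         paste(.DE_STATS, collapse = ", "))
  if (is(counts, "SummarizedExperiment")) {
    tissue <- SummarizedExperiment::colData(counts)$tissue
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (is.null(tissue)) stop("tissue labels required")
  stopifnot(length(contrast) == 2, length(tissue) == ncol(counts))
  ia <- which(tissue == contrast[1]); ib <- which(tissue == contrast[2])
  if (!length(ia) || !length(ib))
    stop("contrast tissues not found in design: ",
         paste(contrast, collapse = ", "))
  N <- colSums(counts)
  if (any(N == 0)) stop("zero library size")
  S <- mean(N)
  norm <- sweep(counts, 2, S / N, "*")
  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mA + pseudoCount) / (mB + pseudoCount))

  if (stat == "nbz") {
    phi <- .pooledDispersion(norm, list(ia, ib))
    vA <- (1 / (mA + pseudoCount) + phi) / length(ia)
    vB <- (1 / (mB + pseudoCount) + phi) / length(ib)
    z <- (log(mA + pseudoCount) - log(mB + pseudoCount)) / sqrt(vA + vB)
    pvalue <- 2 * stats::pnorm(-abs(z))
  } else {
    kA <- round(rowSums(counts[, ia, drop = FALSE]))
    kB <- round(rowSums(counts[, ib, drop = FALSE]))
    prob <- sum(N[ia]) / sum(N[c(ia, ib)])
    pvalue <- vapply(seq_along(kA), function(i) {
      tot <- kA[i] + kB[i]
      if (tot == 0) return(1)
      stats::binom.test(kA[i], tot, p = prob)$p.value
    }, numeric(1))
  }
  qvalue <- bhAdjust(pvalue)
  significant <- abs(log2fc) >= log2(fcCutoff) & qvalue <= qCutoff
  direction <- ifelse(!significant, "none", ifelse(log2fc > 0, "up", "down"))
  data.frame(
    feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    contrast = paste0(contrast[1], "-vs-", contrast[2]),
    log2fc = log2fc, pvalue = pvalue, qvalue = qvalue,
    direction = direction, significant = significant, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Method-of-moments common NB dispersion on normalized counts, pooled
# across features and groups as a ratio of sums so that high-count
# features (where the moment estimator is informative) dominate.
.pooledDispersion <- function(norm, groups) {
  num <- 0; den <- 0
  for (g in groups) {
    if (length(g) < 2) next
    m <- rowMeans(norm[, g, drop = FALSE])
    v <- apply(norm[, g, drop = FALSE], 1, stats::var)
    num <- num + sum(v - m, na.rm = TRUE)
    den <- den + sum(m^2, na.rm = TRUE)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of feature rows, the row-ordering step for
#' expression heatmaps.  The default distance is 1 - Pearson correlation
#' across samples with average linkage; a row with zero variance has
#' undefined correlation and its distance to every other row is defined
#' as 1.
#'
#' @param mat Numeric matrix (features x samples), >= 2 rows.
#' @param distance \code{"correlation"} (1 - Pearson) or
#'   \code{"euclidean"}.
#' @param linkage Agglomeration method passed to \code{stats::hclust}.
#' @return An \code{hclust} object (merge tree, heights, leaf order).
#' @export
hierarchicalCluster <- function(mat, distance = c("correlation", "euclidean"),
                                linkage = "average") {
  distance <- match.arg(distance)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows to cluster")
  if (distance == "correlation") {
    cc <- suppressWarnings(stats::cor(t(mat)))
    cc[is.na(cc)] <- 0            # zero-variance rows: distance 1
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(mat)
  }
  stats::hclust(d, method = linkage)
}
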