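#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson coefficient with the exact t-based two-sided p-value
#' (\eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom), the
#' coding/non-coding co-expression (CNC) statistic used for cis-target
#' screening.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Named numeric vector \code{c(r =, p =)}.
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  # guard |r| = 1 exactly: t is infinite, p underflows to 0
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  c(r = r, p = min(p, 1))
}

#' Cis-target prediction for differentially expressed lncRNAs
#'
#' A gene is a cis-target candidate of an lncRNA when (i) both are
#' differentially expressed, (ii) the gene span overlaps the lncRNA span
#' or lies within \code{window} bases up- or downstream of it (default
#' 100 kb), and (iii) their expression profiles are significantly
#' correlated (Pearson p < \code{alpha}, default 0.01) across all samples.
#' Correlation is computed across every sample (tissues x replicates)
#' rather than across tissue means.
#'
#' @param deLnc,deGenes Character vectors: differentially expressed lncRNA
#'   and gene ids (any contrast).
#' @param rpkm RPKM matrix (features x samples) containing rows for every
#'   queried feature, or a \code{SummarizedExperiment} with an
#'   \code{"rpkm"} assay.
#' @param lncSpans,geneSpans Named \code{GRanges} spans (or
#'   \linkS4class{TranscriptSet}s) for the lncRNAs and genes.
#' @param window Maximum gap in bases (strictly between spans).
#' @param alpha Correlation p-value cutoff.
#' @param positiveOnly If \code{TRUE}, keep only positively correlated
#'   pairs.
#' @return A data.frame with columns \code{lnc_id}, \code{gene_id},
#'   \code{r}, \code{p}, \code{relation} (\code{overlap} or
#'   \code{within_window}), \code{gap_bp}.
#' @export
predictCisTargets <- function(deLnc, deGenes, rpkm, lncSpans, geneSpans,
                              window = 100000, alpha = 0.01,
                              positiveOnly = FALSE) {
  if (is(rpkm, "SummarizedExperiment"))
    rpkm <- SummarizedExperiment::assay(rpkm, "rpkm")
  if (is(lncSpans, "TranscriptSet")) lncSpans <- txSpans(lncSpans)
  if (is(geneSpans, "TranscriptSet")) geneSpans <- txSpans(geneSpans)
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      r = numeric(), p = numeric(), relation = character(),
                      gap_bp = numeric())
  lncSpans <- lncSpans[names(lncSpans) %in% deLnc]
  geneSpans <- geneSpans[names(geneSpans) %in% deGenes]
  if (!length(lncSpans) || !length(geneSpans)) return(empty)
  miss <- setdiff(c(names(lncSpans), names(geneSpans)), rownames(rpkm))
  if (length(miss))
    stop("expression rows missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  hits <- GenomicRanges::findOverlaps(lncSpans, geneSpans, maxgap = window,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- overlapBp(lncSpans[qi], geneSpans[si])
  gap <- gapDistance(lncSpans[qi], geneSpans[si])
  keep <- ov > 0 | gap <= window
  qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]; gap <- gap[keep]
  if (!length(qi)) return(empty)
  rp <- t(vapply(seq_along(qi), function(k) {
    pearsonWithP(rpkm[names(lncSpans)[qi[k]], ],
                 rpkm[names(geneSpans)[si[k]], ])
  }, c(r = 0, p = 0)))
  sel <- rp[, "p"] < alpha
  if (positiveOnly) sel <- sel & rp[, "r"] > 0
  data.frame(lnc_id = names(lncSpans)[qi[sel]],
             gene_id = names(geneSpans)[si[sel]],
             r = rp[sel, "r"], p = rp[sel, "p"],
             relation = ifelse(ov[sel] > 0, "overlap", "within_window"),
             gap_bp = ifelse(ov[sel] > 0, 0, gap[sel]),
             row.names = NULL)
}
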