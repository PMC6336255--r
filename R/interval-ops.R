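#' Pairwise overlap and gap between genomic intervals
#'
#' Element-wise interval algebra on pairs of genomic ranges, the substrate
#' for positional classification and the cis-window rule.  Coordinates
#' follow the GenomicRanges convention (1-based, closed).
#'
#' \code{overlapBp(a, b)} returns the number of shared bases: with matching
#' chromosomes it is \code{max(0, min(end) - max(start) + 1)}; intervals on
#' different chromosomes share 0 bases.  Adjacent (bookended) intervals
#' share 0 bases: "overlap" means shared bases, so classification treats
#' them as non-overlapping.
#'
#' \code{gapDistance(a, b)} returns the number of bases strictly between the
#' two intervals: 0 if they overlap or are adjacent, and \code{Inf} for
#' intervals on different chromosomes (never a finite number).
#'
#' Both are symmetric, and for any pair on one chromosome exactly one of
#' \code{overlapBp > 0}, \code{gapDistance > 0}, or both equal to 0
#' (adjacency) holds.
#'
#' @param a,b \code{GRanges} of equal length (or length 1, recycled).
#'   Strand is ignored.
#' @return \code{overlapBp}: integer vector of shared base counts.
#'   \code{gapDistance}: numeric vector (\code{Inf} marks different
#'   chromosomes).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' overlapBp(a, b)     # 50
#' gapDistance(a, b)   # 0
#' @export
overlapBp <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  pmax(ov, 0L)
}

#' @rdname overlapBp
#' @export
gapDistance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  gap <- pmax(start(a), start(b)) - pmin(end(a), end(b)) - 1
  gap <- pmax(gap, 0)
  gap[as.character(seqnames(a)) != as.character(seqnames(b))] <- Inf
  gap
}
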