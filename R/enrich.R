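#' Hypergeometric enrichment tail probability
#'
#' Exact upper-tail probability that at least \code{m} of the \code{n}
#' differentially expressed genes fall in a term of \code{M} annotated
#' genes, out of \code{N} annotated genes in total:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}}
#' Computed as the complementary tail sum
#' \eqn{\sum_{i=m}^{\min(n,M)}} of the same terms (mathematically
#' identical, numerically stable), with binomial coefficients evaluated in
#' log space.  \code{m = 0} gives the empty sum, \eqn{P = 1}.
#'
#' @param m DE genes annotated to the term.
#' @param N All annotated genes.
#' @param M Genes annotated to the term.
#' @param n DE genes among \code{N}.
#' @return The enrichment p-value in [0, 1].  Vectorized over \code{m},
#'   \code{M}.
#' @examples
#' hyperTailP(3, N = 10, M = 4, n = 5)  # 66/252
#' @export
hyperTailP <- function(m, N, M, n) {
  ln <- max(length(m), length(M), length(N), length(n))
  m <- rep_len(m, ln); M <- rep_len(M, ln)
  N <- rep_len(N, ln); n <- rep_len(n, ln)
  if (any(M > N) || any(n > N)) stop("need M <= N and n <= N")
  if (any(m > M) || any(m > n)) stop("need m <= min(n, M)")
  if (any(c(m, M, N, n) < 0)) stop("counts must be non-negative")
  vapply(seq_len(ln), function(k) {
    if (m[k] == 0) return(1)
    i <- m[k]:min(n[k], M[k])
    if (m[k] > min(n[k], M[k])) return(0)
    p <- sum(exp(lchoose(M[k], i) + lchoose(N[k] - M[k], n[k] - i) -
                 lchoose(N[k], n[k])))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Term enrichment of a DE gene set
#'
#' Hypergeometric over-representation test of a differentially expressed
#' (or cis-target) gene set against term annotations (GO terms, KEGG
#' pathways), with BH adjustment across terms.  \code{P} is exactly
#' \code{1 - CDF(m - 1)} of the hypergeometric distribution and is
#' non-increasing in \code{m} at fixed margins.
#'
#' @param termMap A data.frame with columns \code{gene_id}, \code{term_id}
#'   and optionally \code{term_name}, \code{namespace}.
#' @param deSet Character vector of DE gene ids; must be a subset of
#'   \code{background}.
#' @param background Character vector of annotated background gene ids;
#'   defaults to all genes in \code{termMap}.
#' @return A data.frame sorted by \code{P} with columns \code{term_id},
#'   \code{term_name}, \code{N}, \code{n}, \code{M}, \code{m}, \code{P},
#'   \code{q}.
#' @export
enrichTerms <- function(termMap, deSet, background = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(termMap)))
  if (is.null(background)) background <- unique(termMap$gene_id)
  if (!all(deSet %in% background))
    stop("deSet must be a subset of the background")
  termMap <- termMap[termMap$gene_id %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(unique(deSet))
  by_term <- split(termMap$gene_id, termMap$term_id)
  M <- vapply(by_term, function(g) length(unique(g)), integer(1))
  m <- vapply(by_term, function(g) length(intersect(unique(g), deSet)),
              integer(1))
  if (any(M < 1)) stop("every term must annotate at least one gene")
  P <- hyperTailP(m, N = N, M = M, n = n)
  nm <- if ("term_name" %in% names(termMap)) {
    stats::setNames(termMap$term_name, termMap$term_id)[names(by_term)]
  } else names(by_term)
  out <- data.frame(term_id = names(by_term), term_name = unname(nm),
                    N = N, n = n, M = unname(M), m = unname(m),
                    P = unname(P), q = unname(bhAdjust(P)), row.names = NULL)
  out[order(out$P, out$term_id), , drop = FALSE]
}
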