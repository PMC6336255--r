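# Independent brute-force oracles used across the suite.  Each one is a
# direct, unoptimized restatement of the definition it checks, kept free
# of any code path from the package implementation.

gr1 <- function(chrom, start, end, strand = "+") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

# positional class from raw span coordinates: test the three containment
# relations and the strand/side configurations directly
bruteClassify <- function(ls, le, lstr, ps, pe, pstr) {
  shared <- min(le, pe) - max(ls, ps) + 1
  if (shared > 0) {
    partner_inside <- ps >= ls && pe <= le
    lnc_inside <- ls >= ps && le <= pe
    if (partner_inside) return("containing")   # span equality lands here
    if (lnc_inside) return("nested")
    return("overlapping")
  }
  if (lstr == pstr) return("same_strand")
  left_is_lnc <- ls <= ps
  left_strand <- if (left_is_lnc) lstr else pstr
  if (left_strand == "+") "convergent" else "divergent"
}

# definitional BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
bruteHyperTail <- function(m, N, M, n) {
  if (m == 0) return(1)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= M)   # genes 1..M carry the term
  mean(overlap >= m)
}

# longest sense-strand ORF by scanning every start position
bruteOrf <- function(s) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(s)
  best <- 0
  for (i in seq_len(max(n - 5, 0))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      if (substr(s, j, j + 2) %in% stops) {
        best <- max(best, j + 2 - i + 1)
        break
      }
      j <- j + 3
    }
  }
  best
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
bruteUPGMA <- function(d) {
  d <- as.matrix(d)
  active <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      h <- mean(d[active[[i]], active[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- active[-c(best[2], best[3])]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

# Venn region sizes by tallying each element's membership vector
bruteVennCounts <- function(sets) {
  ids <- unique(unlist(sets))
  code <- vapply(ids, function(x)
    paste(ifelse(vapply(sets, function(s) x %in% s, logical(1)), "1", "0"),
          collapse = ""), character(1))
  table(code)
}

# ceRNA acceptance by triple loop over all (lnc, mir, mrna) combinations
bruteTriplets <- function(lncT, mrnaT, trends) {
  tr <- as.matrix(trends[, -1, drop = FALSE])
  rownames(tr) <- trends$feature_id
  out <- list()
  for (l in unique(lncT$target_id)) for (mi in unique(lncT$mirna_id)) {
    if (!any(lncT$target_id == l & lncT$mirna_id == mi)) next
    for (mr in unique(mrnaT$target_id)) {
      if (!any(mrnaT$target_id == mr & mrnaT$mirna_id == mi)) next
      if (!all(c(l, mi, mr) %in% rownames(tr))) next
      ok <- FALSE
      for (ct in colnames(tr)) {
        sl <- tr[l, ct]; sm <- tr[mr, ct]; si <- tr[mi, ct]
        if (sl != 0 && sm == sl && si == -sl) ok <- TRUE
      }
      out[[length(out) + 1]] <- data.frame(
        lnc_id = l, mirna_id = mi, mrna_id = mr, accepted = ok)
    }
  }
  if (!length(out)) return(data.frame(lnc_id = character(),
                                      mirna_id = character(),
                                      mrna_id = character(),
                                      accepted = logical()))
  do.call(rbind, out)
}

# random exon-structured TranscriptSet on a small genome
randomTranscriptDf <- function(n, chroms = c("chr1", "chr2"),
                               span = 10000) {
  rows <- lapply(seq_len(n), function(i) {
    s <- sample(span, 1)
    w <- sample(100:800, 1)
    data.frame(chrom = sample(chroms, 1),
               start = s, end = s + w,
               strand = sample(c("+", "-"), 1),
               transcript_id = sprintf("t%03d", i),
               gene_id = sprintf("g%03d", i))
  })
  do.call(rbind, rows)
}
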