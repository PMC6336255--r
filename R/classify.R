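.GENIC_CLASSES <- c("overlapping", "containing", "nested")
.INTERGENIC_CLASSES <- c("same_strand", "convergent", "divergent")
.ALL_CLASSES <- c(.GENIC_CLASSES, .INTERGENIC_CLASSES)

#' Positional class of an lncRNA relative to its partner gene
#'
#' Assigns one of the six positional classes from the lncRNA span and the
#' partner-gene span (whole-transcript spans, not exon unions).
#'
#' Genic (the spans share at least one base), by containment geometry and
#' irrespective of strand:
#' \itemize{
#'   \item \code{containing} — the partner span lies inside the lncRNA span;
#'   \item \code{nested} — the lncRNA span lies inside the partner span;
#'   \item \code{overlapping} — partial overlap (neither contains the other).
#' }
#' Containment is non-strict; identical spans classify as \code{containing}
#' (the tie with \code{nested} is resolved deterministically in favour of
#' \code{containing}).
#'
#' Intergenic (no shared base, including adjacency), by strand geometry:
#' \itemize{
#'   \item \code{same_strand} — both on the same strand (same transcription
#'     direction);
#'   \item \code{convergent} — opposite strands, both transcribing toward
#'     the gap (the left-hand feature on \code{+});
#'   \item \code{divergent} — opposite strands, transcribing away from the
#'     gap (the left-hand feature on \code{-}).
#' }
#'
#' @param lnc,partner \code{GRanges} of equal length (element-wise pairs) on
#'   the same chromosome, strands \code{+}/\code{-}.
#' @return Character vector of classes.
#' @export
classifyPosition <- function(lnc, partner) {
  n <- max(length(lnc), length(partner))
  lnc <- rep(lnc, length.out = n)
  partner <- rep(partner, length.out = n)
  if (any(as.character(seqnames(lnc)) != as.character(seqnames(partner))))
    stop("lncRNA and partner on different chromosomes")
  sl <- as.character(strand(lnc)); sp <- as.character(strand(partner))
  if (any(!(sl %in% c("+", "-")) | !(sp %in% c("+", "-"))))
    stop("strand must be '+' or '-'")
  ov <- overlapBp(lnc, partner)
  cls <- character(n)

  genic <- ov > 0L
  contains <- start(lnc) <= start(partner) & end(partner) <= end(lnc)
  nested <- start(partner) <= start(lnc) & end(lnc) <= end(partner)
  cls[genic & contains] <- "containing"          # equality resolves here
  cls[genic & nested & !contains] <- "nested"
  cls[genic & !contains & !nested] <- "overlapping"

  inter <- !genic
  same <- sl == sp
  cls[inter & same] <- "same_strand"
  # left-hand feature of the pair; for opposite strands, '+' on the left
  # means both transcribe toward the gap
  left_strand <- ifelse(start(lnc) <= start(partner), sl, sp)
  cls[inter & !same & left_strand == "+"] <- "convergent"
  cls[inter & !same & left_strand == "-"] <- "divergent"
  cls
}

#' Assign a partner gene to each lncRNA
#'
#' For every lncRNA, the RNA partner is the gene whose span overlaps the
#' lncRNA span by the most bases; with no overlapping gene, the nearest
#' gene by gap distance within \code{maxGap} (default 100 kb, the cis
#' window); lncRNAs with no gene in reach stay unclassified.  Ties (equal
#' overlap, or equidistant flanking genes) break toward the gene with the
#' smaller start coordinate, then lexicographically by id, so the
#' assignment is deterministic.
#'
#' @param lnc A \linkS4class{TranscriptSet} (or \code{GRanges} of spans) of
#'   lncRNAs.
#' @param genes A \linkS4class{TranscriptSet} (or named \code{GRanges} of
#'   spans) of candidate partner genes.
#' @param maxGap Maximum gap (bases strictly between spans) for a
#'   non-overlapping partner.
#' @return A data.frame with columns \code{lnc_id}, \code{partner_gene_id}
#'   (\code{NA} when unclassified), \code{class} (one of the six classes or
#'   \code{"unclassified"}), \code{overlap_bp}, \code{gap_bp} (\code{Inf}
#'   when unclassified).
#' @export
assignPartners <- function(lnc, genes, maxGap = 100000) {
  lsp <- if (is(lnc, "TranscriptSet")) txSpans(lnc) else lnc
  gsp <- if (is(genes, "TranscriptSet")) txSpans(genes) else genes
  if (is.null(names(gsp))) stop("gene spans must be named")
  out <- data.frame(lnc_id = names(lsp),
                    partner_gene_id = NA_character_,
                    class = "unclassified",
                    overlap_bp = 0L, gap_bp = Inf, row.names = NULL)
  if (!length(gsp) || !length(lsp)) return(out)
  # candidate pairs within maxGap (includes all overlaps)
  hits <- GenomicRanges::findOverlaps(lsp, gsp, maxgap = maxGap,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- overlapBp(lsp[qi], gsp[si])
  gap <- gapDistance(lsp[qi], gsp[si])
  cand <- data.frame(q = qi, s = si, ov = ov, gap = gap,
                     g_start = start(gsp)[si], g_id = names(gsp)[si])
  # drop non-overlapping candidates beyond maxGap (findOverlaps maxgap
  # already enforces this; kept as a guard) and self-pairs by id
  cand <- cand[cand$ov > 0L | cand$gap <= maxGap, ]
  cand <- cand[names(lsp)[cand$q] != cand$g_id, ]
  if (!nrow(cand)) return(out)
  # rank: overlapping genes (by decreasing overlap) beat nearby genes (by
  # increasing gap); ties by smaller start, then id
  ord <- order(cand$q, cand$ov == 0L, -cand$ov, cand$gap,
               cand$g_start, cand$g_id)
  cand <- cand[ord, ]
  best <- cand[!duplicated(cand$q), ]
  out$partner_gene_id[best$q] <- best$g_id
  out$overlap_bp[best$q] <- best$ov
  out$gap_bp[best$q] <- best$gap
  out$class[best$q] <- classifyPosition(lsp[best$q], gsp[best$s])
  out
}

#' Class summaries for classified lncRNAs
#'
#' Summary tables for a set of partner assignments: class counts and
#' proportions, class-by-length-bin counts, and class density per
#' chromosome — the inputs for class pie charts, length histograms and
#' per-chromosome density plots.
#'
#' @param assignments Output of [assignPartners()].
#' @param lnc The \linkS4class{TranscriptSet} (or spans) the assignments
#'   were computed from.
#' @param expressed Optional named list of per-tissue expressed feature
#'   sets (from [expressedSets()]); adds per-tissue class proportions.
#' @param lengthBreaks Breakpoints (bp) for length binning.
#' @return A list with data.frames \code{class_counts} (class, n,
#'   proportion over classified lncRNAs), \code{length_bins} (class x
#'   length-bin counts), \code{chrom_density} (chromosome x class counts)
#'   and, with \code{expressed}, \code{class_by_tissue} (tissue x class
#'   counts and within-tissue proportions).
#' @export
classSummaries <- function(assignments, lnc, expressed = NULL,
                           lengthBreaks = c(0, 500, 1000, 1500, 2000, 3000, Inf)) {
  cls <- assignments$class[assignments$class != "unclassified"]
  if (!length(cls)) {
    empty <- data.frame()
    return(list(class_counts = empty, length_bins = empty,
                chrom_density = empty, class_by_tissue = empty))
  }
  keep <- assignments$class != "unclassified"
  a <- assignments[keep, ]
  counts <- as.data.frame(table(factor(a$class, .ALL_CLASSES)),
                          stringsAsFactors = FALSE)
  names(counts) <- c("class", "n")
  counts$proportion <- counts$n / sum(counts$n)
  if (is(lnc, "TranscriptSet")) {
    lens <- unname(txLengths(lnc)[a$lnc_id])
    chroms <- as.character(seqnames(txSpans(lnc)))[match(a$lnc_id, transcriptIds(lnc))]
  } else {
    lens <- width(lnc)[match(a$lnc_id, names(lnc))]
    chroms <- as.character(seqnames(lnc))[match(a$lnc_id, names(lnc))]
  }
  bin <- cut(lens, lengthBreaks, include.lowest = TRUE)
  length_bins <- as.data.frame(table(class = factor(a$class, .ALL_CLASSES),
                                     length_bin = bin),
                               stringsAsFactors = FALSE)
  chrom_density <- as.data.frame(table(chrom = chroms,
                                       class = factor(a$class, .ALL_CLASSES)),
                                 stringsAsFactors = FALSE)
  class_by_tissue <- NULL
  if (!is.null(expressed)) {
    class_by_tissue <- do.call(rbind, lapply(names(expressed), function(t) {
      sub <- a[a$lnc_id %in% expressed[[t]], ]
      tab <- as.data.frame(table(class = factor(sub$class, .ALL_CLASSES)),
                           stringsAsFactors = FALSE)
      names(tab)[2] <- "n"
      tab$proportion <- if (nrow(sub)) tab$n / nrow(sub) else 0
      cbind(tissue = t, tab)
    }))
  }
  list(class_counts = counts, length_bins = length_bins,
       chrom_density = chrom_density, class_by_tissue = class_by_tissue)
}
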