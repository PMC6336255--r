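.CONTRASTS <- c("flower-vs-leaf", "flower-vs-root", "leaf-vs-root")

#' Cross-tissue expression trend profiles
#'
#' Condenses per-contrast differential expression results into one signed
#' trend vector per feature: \code{+1}/\code{-1} where the feature is
#' significantly up/down in that contrast, \code{0} otherwise.  These
#' profiles drive the ceRNA trend-consistency rule.
#'
#' @param de A data.frame as returned by [deTest()], stacked over all
#'   contrasts of interest (typically the three tissue pairs).
#' @param contrasts Character vector of contrast labels that must all be
#'   present.
#' @return A data.frame with \code{feature_id} and one signed integer
#'   column per contrast.
#' @export
buildTrends <- function(de, contrasts = NULL) {
  stopifnot(all(c("feature_id", "contrast", "log2fc", "significant")
                %in% names(de)))
  if (is.null(contrasts)) contrasts <- unique(de$contrast)
  miss <- setdiff(contrasts, unique(de$contrast))
  if (length(miss))
    stop("missing DE results for contrast(s): ", paste(miss, collapse = ", "))
  de <- de[de$contrast %in% contrasts, ]
  feats <- unique(de$feature_id)
  out <- data.frame(feature_id = feats, row.names = NULL)
  for (ct in contrasts) {
    sub <- de[de$contrast == ct, ]
    sgn <- ifelse(sub$significant, sign(sub$log2fc), 0L)
    out[[ct]] <- as.integer(sgn[match(feats, sub$feature_id)])
    out[[ct]][is.na(out[[ct]])] <- 0L
  }
  out
}

#' Build the lncRNA-miRNA-mRNA ceRNA network
#'
#' A candidate triplet is any (lncRNA, miRNA, mRNA) where the miRNA
#' targets both the lncRNA and the mRNA (a shared miRNA response element).
#' A candidate is \emph{accepted} when at least one contrast shows the
#' ceRNA expression pattern: the lncRNA is differentially expressed
#' (trend sign non-zero), the mRNA trend equals the lncRNA trend, and the
#' miRNA trend is opposite — removing false-positive candidates whose
#' miRNA moves with, rather than against, its targets.  With
#' \code{strict = TRUE} every contrast in which the lncRNA is DE must
#' qualify.
#'
#' Target tables from multiple predictors are unioned by default;
#' \code{combine = "intersection"} keeps only miRNA-target links reported
#' by every source present in the table.
#'
#' @param lncTargets,mrnaTargets Data.frames with columns \code{mirna_id},
#'   \code{target_id} and optionally \code{source}.
#' @param trends Trend profiles from [buildTrends()] covering every
#'   feature named in the target tables (features without a profile are
#'   skipped and counted in \code{attr(,"skipped")}).
#' @param strict Require all lncRNA-DE contrasts to qualify.
#' @param combine \code{"union"} or \code{"intersection"} across predictor
#'   sources.
#' @return A data.frame of candidate triplets with columns \code{lnc_id},
#'   \code{mirna_id}, \code{mrna_id}, \code{shared_contrasts}
#'   (comma-joined), \code{accepted}; the number of skipped features is
#'   attached as attribute \code{"skipped"}.
#' @export
buildCernaNetwork <- function(lncTargets, mrnaTargets, trends,
                              strict = FALSE,
                              combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  for (tb in list(lncTargets, mrnaTargets))
    stopifnot(all(c("mirna_id", "target_id") %in% names(tb)))
  lncT <- .combineSources(lncTargets, combine)
  mrnaT <- .combineSources(mrnaTargets, combine)
  contrasts <- setdiff(names(trends), "feature_id")
  tr <- as.matrix(trends[, contrasts, drop = FALSE])
  rownames(tr) <- trends$feature_id
  named <- unique(c(lncT$target_id, mrnaT$target_id, lncT$mirna_id,
                    mrnaT$mirna_id))
  skipped <- sum(!named %in% rownames(tr))
  lncT <- lncT[lncT$target_id %in% rownames(tr) &
               lncT$mirna_id %in% rownames(tr), ]
  mrnaT <- mrnaT[mrnaT$target_id %in% rownames(tr) &
                 mrnaT$mirna_id %in% rownames(tr), ]
  cand <- merge(lncT, mrnaT, by = "mirna_id",
                suffixes = c("_lnc", "_mrna"))
  if (!nrow(cand)) {
    out <- data.frame(lnc_id = character(), mirna_id = character(),
                      mrna_id = character(), shared_contrasts = character(),
                      accepted = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }
  lnc_s <- tr[cand$target_id_lnc, , drop = FALSE]
  mir_s <- tr[cand$mirna_id, , drop = FALSE]
  mrna_s <- tr[cand$target_id_mrna, , drop = FALSE]
  qual <- lnc_s != 0 & mrna_s == lnc_s & mir_s == -lnc_s
  lnc_de <- lnc_s != 0
  accepted <- if (strict) {
    rowSums(lnc_de) > 0 & rowSums(qual) == rowSums(lnc_de)
  } else rowSums(qual) > 0
  shared <- vapply(seq_len(nrow(qual)), function(i)
    paste(contrasts[qual[i, ]], collapse = ","), character(1))
  out <- data.frame(lnc_id = cand$target_id_lnc,
                    mirna_id = cand$mirna_id,
                    mrna_id = cand$target_id_mrna,
                    shared_contrasts = shared,
                    accepted = accepted, row.names = NULL)
  out <- out[order(out$lnc_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

.combineSources <- function(tb, combine) {
  key <- paste(tb$mirna_id, tb$target_id, sep = "\r")
  if (combine == "intersection" && "source" %in% names(tb) &&
      length(unique(tb$source)) > 1) {
    n_src <- length(unique(tb$source))
    per_key <- tapply(tb$source, key, function(s) length(unique(s)))
    tb <- tb[per_key[key] == n_src, , drop = FALSE]
    key <- paste(tb$mirna_id, tb$target_id, sep = "\r")
  }
  unique(tb[, c("mirna_id", "target_id"), drop = FALSE])
}

#' Export a ceRNA network for network viewers
#'
#' Writes the accepted triplets as a SIF edge file
#' (\code{miRNA TAB targets TAB lncRNA/mRNA}) and a node-attribute TSV
#' (\code{id}, \code{type}).  Edges are deduplicated (a miRNA-mRNA edge
#' shared by several triplets appears once) and both files are sorted, so
#' re-export of the same network is byte-identical.
#'
#' @param triplets Output of [buildCernaNetwork()]; only rows with
#'   \code{accepted == TRUE} are exported.
#' @param sifPath,nodePath Output paths for the SIF and node table.
#' @return Invisibly, a list with the edge and node data.frames.
#' @export
exportNetwork <- function(triplets, sifPath, nodePath) {
  acc <- triplets[triplets$accepted, , drop = FALSE]
  edges <- unique(rbind(
    data.frame(from = acc$mirna_id, interaction = "targets", to = acc$lnc_id),
    data.frame(from = acc$mirna_id, interaction = "targets", to = acc$mrna_id)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  nodes <- unique(rbind(
    data.frame(id = acc$lnc_id, type = "lncRNA"),
    data.frame(id = acc$mirna_id, type = "miRNA"),
    data.frame(id = acc$mrna_id, type = "mRNA")))
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%s", edges$from, edges$interaction, edges$to),
             sifPath)
  utils::write.table(nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}
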