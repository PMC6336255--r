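#' Configuration for a synthetic lncRNA study
#'
#' Defines the shape of a fully self-contained synthetic study: a toy
#' genome carrying coding genes and lncRNAs planted in each of the six
#' positional classes, negative-binomial counts for a three-tissue,
#' three-replicate design with planted differential expression, planted
#' correlated cis pairs within the 100-kb window, planted ceRNA triplets
#' (lncRNA/mRNA trends equal, miRNA trend opposite) with concordant-trend
#' decoys, and decoy transcripts each violating exactly one step of the
#' novelty filter cascade.  The seed fully determines every output.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param nChroms Number of chromosomes.
#' @param chromLength Chromosome length in bp; \code{NULL} sizes the genome
#'   to fit all planted features without unintended proximity.  Feature
#'   blocks are spaced so that features of different blocks are always
#'   farther apart than the cis window.
#' @param nCodingGenes Total coding genes; the first \code{6 * nLncPerClass}
#'   serve as RNA partners of the planted lncRNAs.
#' @param nLncPerClass Planted lncRNAs per positional class (the first of
#'   each class is annotated as a known lncRNA, the rest are novel).
#' @param tissues Tissue names (three by default: flower, leaf, root).
#' @param nReps Biological replicates per tissue.
#' @param librarySize Expected total reads per sample.
#' @param nbDispersion Negative-binomial dispersion of counts; 0 gives
#'   Poisson noise (the zero-dispersion limit).
#' @param deLog2fc Planted log2 effect size for differentially expressed
#'   features.
#' @param nDecoys Number of cascade decoy transcripts.
#' @param fracFailPerFilter Named fractions over the five cascade steps
#'   (\code{length}, \code{coverage}, \code{known_overlap},
#'   \code{known_lnc_similarity}, \code{coding_potential}) giving each
#'   decoy's planted single violation; must sum to 1.
#' @param nCisPairs Planted correlated lncRNA-gene cis pairs (within the
#'   window, shared latent expression factor).
#' @param nCisNegatives Planted adjacent-but-uncorrelated decoy pairs (both
#'   members DE, orthogonal tissue patterns).
#' @param nCernaTriplets Planted ceRNA triplets, each mirrored by one
#'   concordant-trend decoy miRNA.
#' @param nTissueSpecificLnc Per tissue, lncRNAs expressed in that tissue
#'   only.
#' @return A validated list of class \code{lncflowSimConfig}.
#' @export
simulationConfig <- function(seed = 1, nChroms = 2, chromLength = NULL,
                             nCodingGenes = 40, nLncPerClass = 5,
                             tissues = c("flower", "leaf", "root"),
                             nReps = 3, librarySize = 1e6,
                             nbDispersion = 0.1, deLog2fc = 2,
                             nDecoys = 25,
                             fracFailPerFilter = c(
                               length = 0.2, coverage = 0.2,
                               known_overlap = 0.2,
                               known_lnc_similarity = 0.2,
                               coding_potential = 0.2),
                             nCisPairs = 5, nCisNegatives = 3,
                             nCernaTriplets = 5, nTissueSpecificLnc = 2) {
  cfg <- list(seed = as.integer(seed), nChroms = nChroms,
              chromLength = chromLength, nCodingGenes = nCodingGenes,
              nLncPerClass = nLncPerClass, tissues = tissues, nReps = nReps,
              librarySize = librarySize, nbDispersion = nbDispersion,
              deLog2fc = deLog2fc, nDecoys = nDecoys,
              fracFailPerFilter = fracFailPerFilter, nCisPairs = nCisPairs,
              nCisNegatives = nCisNegatives,
              nCernaTriplets = nCernaTriplets,
              nTissueSpecificLnc = nTissueSpecificLnc)
  counts <- c(nChroms, nCodingGenes, nLncPerClass, nReps, nDecoys,
              nCisPairs, nCisNegatives, nCernaTriplets, nTissueSpecificLnc)
  if (any(counts < 0)) stop("configuration error: counts must be >= 0")
  if (nbDispersion < 0 || librarySize <= 0 || deLog2fc < 0)
    stop("configuration error: invalid noise/effect parameters")
  if (!setequal(names(fracFailPerFilter), .FILTER_STEPS) ||
      abs(sum(fracFailPerFilter) - 1) > 1e-8)
    stop("configuration error: fracFailPerFilter must cover the five ",
         "cascade steps and sum to 1")
  if (length(tissues) != 3)
    stop("configuration error: the planted trend patterns assume 3 tissues")
  nLnc <- 6 * nLncPerClass
  if (nCodingGenes < nLnc + nCernaTriplets)
    stop("configuration error: need nCodingGenes >= 6*nLncPerClass + ",
         "nCernaTriplets")
  nKnown <- if (nLncPerClass > 0) 6 else 0
  nNovel <- nLnc - nKnown
  if (nNovel < nCernaTriplets + nCisPairs + nCisNegatives +
        3 * nTissueSpecificLnc)
    stop("configuration error: not enough novel lncRNAs to plant the ",
         "requested cis/ceRNA/tissue-specific structure")
  class(cfg) <- "lncflowSimConfig"
  cfg
}

.BLOCK_WIDTH <- 30000L
.BLOCK_SPACING <- 250000L   # > 2x the 100-kb cis window + block width

# span geometry of (lncRNA, partner gene) within a block at offset a,
# constructed so the positional classifier must recover the class
.blockGeometry <- function(class, a) {
  switch(class,
    containing  = list(lnc = c(a, a + 2999L, "+"), gene = c(a + 500L, a + 1499L, "+")),
    nested      = list(lnc = c(a + 1000L, a + 2999L, "+"), gene = c(a, a + 4999L, "+")),
    overlapping = list(lnc = c(a + 1000L, a + 3999L, "+"), gene = c(a, a + 1999L, "+")),
    same_strand = list(lnc = c(a + 7000L, a + 8999L, "+"), gene = c(a, a + 1999L, "+")),
    convergent  = list(lnc = c(a, a + 1999L, "+"), gene = c(a + 7000L, a + 8999L, "-")),
    divergent   = list(lnc = c(a + 7000L, a + 8999L, "+"), gene = c(a, a + 1999L, "-")))
}

# two exons inside [s, e] with total spliced width w (w >= 2, even split)
.twoExons <- function(s, e, w) {
  w1 <- w %/% 2L; w2 <- w - w1
  data.frame(start = c(s, e - w2 + 1L), end = c(s + w1 - 1L, e))
}

#' Negative-binomial count matrix from a mean matrix
#'
#' Draws independent counts with the given per-cell means and a common
#' dispersion; dispersion 0 is the Poisson special case.  The building
#' block of the study generator, exported for calibration experiments
#' (null and power simulations).
#'
#' @param mu Matrix of expected counts (features x samples).
#' @param dispersion Common NB dispersion (variance = mu + dispersion *
#'   mu^2).
#' @return Integer-valued matrix, same dimnames as \code{mu}.
#' @export
simulateCounts <- function(mu, dispersion = 0) {
  mu <- as.matrix(mu)
  n <- length(mu)
  cnt <- if (dispersion > 0) {
    stats::rnbinom(n, mu = as.numeric(mu), size = 1 / dispersion)
  } else {
    stats::rpois(n, lambda = as.numeric(mu))
  }
  if (all(cnt < .Machine$integer.max)) cnt <- as.integer(cnt)
  matrix(cnt, nrow = nrow(mu), dimnames = dimnames(mu))
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.patternMult <- function(pattern, tissues, f) {
  mult <- stats::setNames(rep(1, length(tissues)), tissues)
  if (pattern == "flat") return(mult)
  parts <- strsplit(pattern, "_")[[1]]
  tis <- parts[1]; kind <- parts[2]
  if (kind == "up") mult[tis] <- f
  if (kind == "down") mult[tis] <- 1 / f
  if (kind == "only") mult[setdiff(tissues, tis)] <- 0
  mult
}

# planted trend signs (F-vs-L, F-vs-R, L-vs-R order for default tissues)
.patternTrend <- function(pattern, tissues) {
  prs <- utils::combn(tissues, 2)
  f <- .patternMult(pattern, tissues, 2)
  vapply(seq_len(ncol(prs)), function(j) {
    a <- f[prs[1, j]]; b <- f[prs[2, j]]
    if (a > b) 1L else if (a < b) -1L else 0L
  }, integer(1))
}

#' Generate a synthetic lncRNA study with planted ground truth
#'
#' Produces every input of the downstream pipeline — annotation,
#' transcript sequences, a raw count matrix, the coding-evidence table,
#' miRNA target tables and miRNA expression — together with a truth table
#' recording what was planted where.  See [simulationConfig()] for the
#' planted structure.  The same configuration (including seed) always
#' yields byte-identical outputs.
#'
#' @param config A [simulationConfig()].
#' @return A list of class \code{lncflowStudy} with elements
#'   \code{config}, \code{annotation} (\linkS4class{TranscriptSet} of all
#'   transcripts including decoys), \code{sequences}
#'   (\code{DNAStringSet}), \code{counts} (\code{SummarizedExperiment},
#'   coding + lncRNA features), \code{evidence} (data.frame for assembled
#'   transcripts), \code{mirTargetsLnc}, \code{mirTargetsMrna},
#'   \code{mirExpression} (matrix), \code{truth} (per-feature data.frame),
#'   \code{cisPairs}, \code{cernaTriplets}.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "lncflowSimConfig"))
  set.seed(config$seed)
  tissues <- config$tissues
  nLnc <- 6 * config$nLncPerClass
  nPartner <- nLnc
  nStandalone <- config$nCodingGenes - nPartner
  nBlocks <- nLnc + nStandalone + config$nDecoys

  # --- genome layout -------------------------------------------------
  slots_per_chrom <- ceiling(nBlocks / max(config$nChroms, 1))
  needed <- (slots_per_chrom - 1) * .BLOCK_SPACING + .BLOCK_WIDTH + 1000
  chromLength <- config$chromLength
  if (is.null(chromLength)) chromLength <- needed
  if (chromLength < needed)
    stop("configuration error: chromLength ", chromLength,
         " too small; need >= ", needed)
  blk_chrom <- sprintf("chr%d", ((seq_len(nBlocks) - 1) %% config$nChroms) + 1)
  blk_start <- 1L + ((seq_len(nBlocks) - 1) %/% config$nChroms) * .BLOCK_SPACING

  classes6 <- rep(.ALL_CLASSES, each = config$nLncPerClass)
  exon_rows <- list()
  addTx <- function(id, gene, cat, chrom, spans_df, strand) {
    exon_rows[[length(exon_rows) + 1]] <<- data.frame(
      chrom = chrom, start = spans_df$start, end = spans_df$end,
      strand = strand, transcript_id = id, gene_id = gene, category = cat)
  }

  lnc_ids <- sprintf("LNC_%03d", seq_len(nLnc))
  known <- seq_len(nLnc) %in% (match(.ALL_CLASSES, classes6))
  lnc_ids[known] <- sprintf("KLNC_%03d", which(known))
  partner_gene <- sprintf("GENC_%03d", seq_len(nPartner))
  for (i in seq_len(nLnc)) {
    g <- .blockGeometry(classes6[i], blk_start[i])
    lsp <- as.integer(g$lnc[1:2]); gsp <- as.integer(g$gene[1:2])
    lnc_w <- 200L + 50L * ((i - 1L) %% 20L)      # spliced 200..1150 bp
    addTx(lnc_ids[i], lnc_ids[i],
          if (known[i]) "known_lncRNA" else "assembled",
          blk_chrom[i], .twoExons(lsp[1], lsp[2], lnc_w), g$lnc[3])
    addTx(paste0(partner_gene[i], ".1"), partner_gene[i], "known_coding",
          blk_chrom[i], .twoExons(gsp[1], gsp[2], 600L + 30L * (i %% 10L)),
          g$gene[3])
  }
  standalone_gene <- sprintf("GENS_%03d", seq_len(nStandalone))
  for (j in seq_len(nStandalone)) {
    b <- nLnc + j
    s <- blk_start[b]
    addTx(paste0(standalone_gene[j], ".1"), standalone_gene[j],
          "known_coding", blk_chrom[b],
          .twoExons(s, s + 2499L, 900L), if (j %% 2) "+" else "-")
  }

  # --- cascade decoys: exactly one planted violation each ------------
  decoy_ids <- sprintf("DEC_%03d", seq_len(config$nDecoys))
  n_per <- round(config$fracFailPerFilter * config$nDecoys)
  while (sum(n_per) > config$nDecoys) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1
  while (sum(n_per) < config$nDecoys) n_per[which.min(n_per)] <- n_per[which.min(n_per)] + 1
  decoy_step <- rep(names(n_per), n_per)
  for (k in seq_len(config$nDecoys)) {
    b <- nLnc + nStandalone + k
    s <- blk_start[b]
    w <- if (decoy_step[k] == "length") 150L else 500L
    addTx(decoy_ids[k], decoy_ids[k], "assembled", blk_chrom[b],
          data.frame(start = s, end = s + w - 1L), "+")
  }

  exon_df <- do.call(rbind, exon_rows)
  annotation <- makeTranscriptSet(exon_df)

  # --- coding evidence table (assembled transcripts only) ------------
  novel_ids <- lnc_ids[!known]
  asm_ids <- c(novel_ids, decoy_ids)
  n_asm <- length(asm_ids)
  ev <- data.frame(
    transcript_id = asm_ids,
    cpc_score = round(stats::runif(n_asm, -3, -0.5), 3),
    pfam_hit = 0L,
    read_coverage = round(stats::runif(n_asm, 4, 50), 2),
    known_lnc_identity = round(stats::runif(n_asm, 0, 50), 1),
    overlaps_known_coding = 0L)
  ev$known_lnc_identity[seq_len(n_asm) %% 3 == 0] <- NA
  dix <- match(decoy_ids, ev$transcript_id)
  for (k in seq_along(dix)) {
    i <- dix[k]
    switch(decoy_step[k],
      coverage = { ev$read_coverage[i] <- round(stats::runif(1, 0, 2.5), 2) },
      known_overlap = { ev$overlaps_known_coding[i] <- 1L },
      known_lnc_similarity = { ev$known_lnc_identity[i] <- round(stats::runif(1, 91, 99.9), 1) },
      coding_potential = {
        if (k %% 2) ev$cpc_score[i] <- round(stats::runif(1, 0, 3), 3)
        else ev$pfam_hit[i] <- 1L
      },
      length = NULL)
  }

  # --- expression patterns -------------------------------------------
  count_ids <- c(paste0(partner_gene, ".1"), paste0(standalone_gene, ".1"),
                 lnc_ids)
  pattern <- stats::setNames(rep("flat", length(count_ids)), count_ids)
  # planted up-tissues rotate so that no tissue dominates the library
  # composition (library-size normalization then leaves planted fold
  # changes intact)
  rot <- function(i) tissues[1 + (i - 1) %% length(tissues)]

  cerna_lnc <- novel_ids[seq_len(config$nCernaTriplets)]
  cis_lnc <- novel_ids[config$nCernaTriplets + seq_len(config$nCisPairs)]
  cisneg_lnc <- novel_ids[config$nCernaTriplets + config$nCisPairs +
                            seq_len(config$nCisNegatives)]
  spare <- setdiff(novel_ids, c(cerna_lnc, cis_lnc, cisneg_lnc))
  ts_lnc <- stats::setNames(vector("list", length(tissues)), tissues)
  for (t in seq_along(tissues)) {
    take <- seq_len(config$nTissueSpecificLnc)
    ts_lnc[[t]] <- spare[take]
    spare <- spare[-take]
    pattern[ts_lnc[[t]]] <- paste0(tissues[t], "_only")
  }
  cerna_tissue <- rot(seq_along(cerna_lnc))
  pattern[cerna_lnc] <- paste0(cerna_tissue, "_up")
  cerna_mrna <- paste0(standalone_gene[seq_len(config$nCernaTriplets)], ".1")
  pattern[cerna_mrna] <- paste0(cerna_tissue, "_up")
  cis_tissue <- rot(seq_along(cis_lnc))
  pattern[cis_lnc] <- paste0(cis_tissue, "_up")
  # cis partner genes share the lncRNA's pattern; negatives get an
  # orthogonal pattern (DE, but uncorrelated with their lncRNA)
  cis_gene <- paste0(partner_gene[match(cis_lnc, lnc_ids)], ".1")
  pattern[cis_gene] <- paste0(cis_tissue, "_up")
  cisneg_tissue <- rot(seq_along(cisneg_lnc))
  pattern[cisneg_lnc] <- paste0(cisneg_tissue, "_up")
  cisneg_gene <- paste0(partner_gene[match(cisneg_lnc, lnc_ids)], ".1")
  pattern[cisneg_gene] <- paste0(rot(seq_along(cisneg_lnc) + 1), "_up")

  # --- counts ---------------------------------------------------------
  nF <- length(count_ids)
  samples <- paste(rep(tissues, each = config$nReps),
                   seq_len(config$nReps), sep = "_")
  tissue_of <- rep(tissues, each = config$nReps)
  base <- config$librarySize / nF * 2^stats::runif(nF, -1.5, 1.5)
  f <- 2^config$deLog2fc
  mu <- matrix(0, nF, length(samples),
               dimnames = list(count_ids, samples))
  for (i in seq_len(nF))
    mu[i, ] <- base[i] * .patternMult(pattern[i], tissues, f)[tissue_of]
  # shared latent factor for planted cis pairs (correlates the pair
  # beyond the tissue pattern); independent jitter for negatives
  for (p in seq_along(cis_lnc)) {
    latent <- exp(stats::rnorm(length(samples), 0, 0.4))
    mu[cis_lnc[p], ] <- mu[cis_lnc[p], ] * latent
    mu[cis_gene[p], ] <- mu[cis_gene[p], ] * latent
  }
  for (p in seq_along(cisneg_lnc)) {
    mu[cisneg_lnc[p], ] <- mu[cisneg_lnc[p], ] *
      exp(stats::rnorm(length(samples), 0, 0.1))
    mu[cisneg_gene[p], ] <- mu[cisneg_gene[p], ] *
      exp(stats::rnorm(length(samples), 0, 0.1))
  }
  counts <- simulateCounts(mu, config$nbDispersion)
  se <- makeExpressionSE(counts, tissue = tissue_of,
                         replicate = rep(seq_len(config$nReps),
                                         length(tissues)))

  # --- miRNAs ----------------------------------------------------------
  nTrip <- config$nCernaTriplets
  mir_true <- sprintf("mir-%03d", seq_len(nTrip))
  mir_decoy <- sprintf("mir-%03d", nTrip + seq_len(nTrip))
  mir_flat <- sprintf("mir-%03d", 2 * nTrip + seq_len(2))
  mir_ids <- c(mir_true, mir_decoy, mir_flat)
  # true miRNAs run opposite to their triplet's lncRNA/mRNA; decoy miRNAs
  # run with it (concordant trend, must be rejected by the network rule)
  mir_pattern <- stats::setNames(
    c(paste0(cerna_tissue, "_down"), paste0(cerna_tissue, "_up"),
      rep("flat", length(mir_flat))), mir_ids)
  mir_base <- 2e4 * 2^stats::runif(length(mir_ids), -1, 1)
  mir_mu <- matrix(0, length(mir_ids), length(samples),
                   dimnames = list(mir_ids, samples))
  for (i in seq_along(mir_ids))
    mir_mu[i, ] <- mir_base[i] *
      .patternMult(mir_pattern[i], tissues, f)[tissue_of]
  mirExpression <- simulateCounts(mir_mu, config$nbDispersion)

  mirTargetsLnc <- rbind(
    data.frame(mirna_id = mir_true, target_id = cerna_lnc,
               target_type = "lncRNA", source = "psRNATarget",
               score = round(stats::runif(nTrip, 1, 5), 2)),
    data.frame(mirna_id = mir_decoy, target_id = cerna_lnc,
               target_type = "lncRNA", source = "psRobot",
               score = round(stats::runif(nTrip, 1, 5), 2)))
  mirTargetsMrna <- rbind(
    data.frame(mirna_id = mir_true, target_id = cerna_mrna,
               target_type = "mRNA", source = "miranda",
               score = round(stats::runif(nTrip, 140, 180), 1)),
    data.frame(mirna_id = mir_decoy, target_id = cerna_mrna,
               target_type = "mRNA", source = "TargetScan",
               score = round(stats::runif(nTrip, 140, 180), 1)),
    # one-sided extra target rows never make a triplet
    data.frame(mirna_id = mir_flat, target_id = cerna_mrna[1],
               target_type = "mRNA", source = "miranda",
               score = round(stats::runif(length(mir_flat), 140, 180), 1)))

  # --- sequences -------------------------------------------------------
  all_ids <- transcriptIds(annotation)
  lens <- txLengths(annotation)
  seqs <- Biostrings::DNAStringSet(
    vapply(unname(lens), .randomDna, character(1)))
  names(seqs) <- all_ids

  # --- truth ----------------------------------------------------------
  trend_names <- apply(utils::combn(tissues, 2), 2,
                       function(p) paste0(p[1], "-vs-", p[2]))
  truthTrend <- function(ids, pat) {
    tm <- t(vapply(pat, .patternTrend, integer(3), tissues = tissues))
    colnames(tm) <- trend_names
    tm
  }
  feat_type <- c(rep("coding", config$nCodingGenes),
                 ifelse(known, "known_lncRNA", "novel_lncRNA"))
  truth <- data.frame(
    feature_id = count_ids,
    type = feat_type,
    class = c(rep(NA_character_, config$nCodingGenes), classes6),
    failed_step = NA_character_,
    pattern = unname(pattern),
    truthTrend(count_ids, pattern),
    cis_partner = NA_character_,
    cis_negative = FALSE,
    check.names = FALSE)
  truth$cis_partner[match(cis_lnc, truth$feature_id)] <- cis_gene
  truth$cis_partner[match(cisneg_lnc, truth$feature_id)] <- cisneg_gene
  truth$cis_negative[match(cisneg_lnc, truth$feature_id)] <- TRUE
  truth_decoys <- data.frame(
    feature_id = decoy_ids, type = "decoy", class = NA_character_,
    failed_step = decoy_step, pattern = NA_character_,
    matrix(NA_integer_, config$nDecoys, 3,
           dimnames = list(NULL, trend_names)),
    cis_partner = NA_character_, cis_negative = FALSE, check.names = FALSE)
  truth_mir <- data.frame(
    feature_id = mir_ids, type = "miRNA", class = NA_character_,
    failed_step = NA_character_, pattern = unname(mir_pattern),
    truthTrend(mir_ids, mir_pattern),
    cis_partner = NA_character_, cis_negative = FALSE, check.names = FALSE)
  truth <- rbind(truth, truth_decoys, truth_mir)

  cisPairs <- data.frame(lnc_id = cis_lnc, gene_id = cis_gene)
  cernaTriplets <- data.frame(lnc_id = cerna_lnc, mirna_id = mir_true,
                              mrna_id = cerna_mrna)

  # --- term annotation with one planted enriched pathway --------------
  gene_tx <- c(paste0(partner_gene, ".1"), paste0(standalone_gene, ".1"))
  de_genes_planted <- unique(c(cis_gene, cisneg_gene, cerna_mrna))
  planted_term <- data.frame(
    gene_id = unique(c(de_genes_planted, gene_tx[1])),
    term_id = "PW_planted", term_name = "planted pathway",
    namespace = "KEGG")
  stripes <- lapply(1:4, function(s) data.frame(
    gene_id = gene_tx[seq(s, length(gene_tx), by = 4)],
    term_id = sprintf("PW_%02d", s),
    term_name = sprintf("background pathway %d", s), namespace = "KEGG"))
  termMap <- rbind(planted_term, do.call(rbind, stripes))

  structure(list(
    config = config, annotation = annotation, sequences = seqs,
    counts = se, evidence = ev, mirTargetsLnc = mirTargetsLnc,
    mirTargetsMrna = mirTargetsMrna, mirExpression = mirExpression,
    termMap = termMap, enrichedTerm = "PW_planted",
    truth = truth, cisPairs = cisPairs, cernaTriplets = cernaTriplets),
    class = "lncflowStudy")
}

#' Write a synthetic study to disk
#'
#' Plain-text serialization of every study component: GTF annotation,
#' FASTA sequences, and TSV tables for counts, evidence, miRNA targets,
#' miRNA expression and truth.
#'
#' @param study A [simulateStudy()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(inherits(study, "lncflowStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeAnnotation(study$annotation, p("annotation.gtf"))
  Biostrings::writeXStringSet(study$sequences, p("transcripts.fa"))
  wtsv <- function(df, f) utils::write.table(
    df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  cnt <- as.data.frame(SummarizedExperiment::assay(study$counts, "counts"))
  cnt <- cbind(feature_id = rownames(cnt), cnt)
  wtsv(cnt, "counts.tsv")
  wtsv(study$evidence, "evidence.tsv")
  wtsv(study$mirTargetsLnc, "mir_targets_lnc.tsv")
  wtsv(study$mirTargetsMrna, "mir_targets_mrna.tsv")
  mir <- cbind(feature_id = rownames(study$mirExpression),
               as.data.frame(study$mirExpression))
  wtsv(mir, "mir_expression.tsv")
  wtsv(study$termMap, "term_map.tsv")
  wtsv(study$truth, "truth_features.tsv")
  wtsv(study$cisPairs, "truth_cis_pairs.tsv")
  wtsv(study$cernaTriplets, "truth_cerna_triplets.tsv")
  cfg <- study$config; class(cfg) <- NULL
  cfg$fracFailPerFilter <- as.list(cfg$fracFailPerFilter)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic study back from disk
#'
#' Inverse of [writeStudy()]; reconstructs the in-memory study object from
#' the plain-text files.
#'
#' @param dir Directory written by [writeStudy()].
#' @return A list of class \code{lncflowStudy}.
#' @export
readStudy <- function(dir) {
  p <- function(f) file.path(dir, f)
  rtsv <- function(f) utils::read.table(p(f), sep = "\t", header = TRUE,
                                        check.names = FALSE,
                                        stringsAsFactors = FALSE)
  cfg <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  cfg$fracFailPerFilter <- unlist(cfg$fracFailPerFilter)
  if (!length(cfg$chromLength)) cfg$chromLength <- NULL
  config <- do.call(simulationConfig, cfg[names(cfg) %in%
                                            names(formals(simulationConfig))])
  cnt <- rtsv("counts.tsv")
  cmat <- as.matrix(cnt[, -1]); rownames(cmat) <- cnt$feature_id
  mir <- rtsv("mir_expression.tsv")
  mmat <- as.matrix(mir[, -1]); rownames(mmat) <- mir$feature_id
  structure(list(
    config = config,
    annotation = readAnnotation(p("annotation.gtf")),
    sequences = readTranscriptSequences(p("transcripts.fa")),
    counts = makeExpressionSE(cmat),
    evidence = rtsv("evidence.tsv"),
    mirTargetsLnc = rtsv("mir_targets_lnc.tsv"),
    mirTargetsMrna = rtsv("mir_targets_mrna.tsv"),
    mirExpression = mmat,
    termMap = rtsv("term_map.tsv"),
    enrichedTerm = "PW_planted",
    truth = rtsv("truth_features.tsv"),
    cisPairs = rtsv("truth_cis_pairs.tsv"),
    cernaTriplets = rtsv("truth_cerna_triplets.tsv")),
    class = "lncflowStudy")
}
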