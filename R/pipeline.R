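.PIPELINE_STAGES <- c("discover", "classify", "quantify", "de", "cis",
                      "enrich", "cerna")

#' Pipeline configuration
#'
#' Aggregates every stage threshold with the standard screen as defaults:
#' minimum transcript length 200 bp, minimum read coverage 3, maximum
#' known-lncRNA identity 90\%, coding-potential cutoff 0, RPKM expression
#' cutoff 1, fold-change cutoff 2, Q-value cutoff 0.01, cis window 100 kb
#' with correlation alpha 0.01.  Stage toggles disable trailing analyses;
#' a stage whose inputs come from a disabled earlier stage is rejected.
#'
#' @param minLength,minCoverage,maxKnownIdentity,cpcCutoff Filter-cascade
#'   thresholds.
#' @param rpkmCutoff Expression-presence RPKM cutoff.
#' @param fcCutoff,qCutoff Differential-expression screen thresholds.
#' @param cisWindow,cisAlpha Cis-target window (bp) and correlation alpha.
#' @param deStat Differential-expression statistic (see [deTest()]).
#' @param seed Seed recorded in the manifest and set before the run.
#' @param stages Character vector of enabled stages, in pipeline order.
#' @return A validated list of class \code{lncflowPipelineConfig}.
#' @export
pipelineConfig <- function(minLength = 200, minCoverage = 3,
                           maxKnownIdentity = 90, cpcCutoff = 0,
                           rpkmCutoff = 1, fcCutoff = 2, qCutoff = 0.01,
                           cisWindow = 100000, cisAlpha = 0.01,
                           deStat = "nbz", seed = 1,
                           stages = .PIPELINE_STAGES) {
  cfg <- list(minLength = minLength, minCoverage = minCoverage,
              maxKnownIdentity = maxKnownIdentity, cpcCutoff = cpcCutoff,
              rpkmCutoff = rpkmCutoff, fcCutoff = fcCutoff,
              qCutoff = qCutoff, cisWindow = cisWindow, cisAlpha = cisAlpha,
              deStat = deStat, seed = as.integer(seed), stages = stages)
  pos <- c("minLength", "minCoverage", "rpkmCutoff", "fcCutoff", "qCutoff",
           "cisWindow", "cisAlpha")
  if (any(unlist(cfg[pos]) <= 0))
    stop("thresholds must be positive: ",
         paste(pos[unlist(cfg[pos]) <= 0], collapse = ", "))
  if (cfg$maxKnownIdentity < 0 || cfg$maxKnownIdentity > 100)
    stop("maxKnownIdentity must be a percent in [0, 100]")
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs <- list(de = "quantify", cis = "de", enrich = "cis", cerna = "de")
  for (s in names(needs))
    if (s %in% stages && !all(needs[[s]] %in% stages))
      stop("stage '", s, "' requires stage '", needs[[s]], "' to be enabled")
  class(cfg) <- "lncflowPipelineConfig"
  cfg
}

#' Run the full lncRNA analysis pipeline
#'
#' Executes the enabled stages in fixed order — discover (filter cascade)
#' -> classify -> quantify (RPKM, expression sets, Venn) -> de (all tissue
#' pairs, lncRNA/gene and miRNA matrices) -> cis -> enrich -> cerna — on a
#' synthetic or file-backed study, writes every stage output as plain text
#' under \code{outdir}, and records a run manifest (config hash, seed,
#' package version, per-stage row counts).  A stage failure aborts with
#' the failing stage named; outputs of completed stages are retained.
#'
#' @param study An \code{lncflowStudy} from [simulateStudy()] or
#'   [readStudy()].
#' @param outdir Output directory.
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with the per-stage results and the
#'   \code{manifest}.
#' @export
runPipeline <- function(study, outdir, config = pipelineConfig()) {
  stopifnot(inherits(study, "lncflowStudy"),
            inherits(config, "lncflowPipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  res <- list()
  counts_rows <- list()
  wtsv <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ann <- study$annotation
  cat_ <- txCategory(ann)
  tissues <- unique(SummarizedExperiment::colData(study$counts)$tissue)
  contrasts <- utils::combn(tissues, 2, simplify = FALSE)

  run_stage("discover", function() {
    asm <- ann[transcriptIds(ann)[cat_ == "assembled"]]
    asm <- deduplicateTranscripts(asm)
    fo <- runFilterCascade(asm, study$evidence,
                           minLength = config$minLength,
                           minCoverage = config$minCoverage,
                           maxKnownIdentity = config$maxKnownIdentity,
                           cpcCutoff = config$cpcCutoff)
    res$discover <<- fo
    counts_rows$discover <<- c(
      n_assembled = nrow(fo), n_novel = sum(fo$passed),
      table(factor(fo$failed_step, c(.FILTER_STEPS, "none"))))
    wtsv(fo, "filter_outcomes.tsv")
  })

  lnc_ids <- function() {
    novel <- if (!is.null(res$discover))
      res$discover$transcript_id[res$discover$passed]
    else transcriptIds(ann)[cat_ == "assembled"]
    c(transcriptIds(ann)[cat_ == "known_lncRNA"], novel)
  }

  run_stage("classify", function() {
    lnc <- ann[lnc_ids()]
    genes <- ann[transcriptIds(ann)[cat_ == "known_coding"]]
    pa <- assignPartners(lnc, genes, maxGap = config$cisWindow)
    res$classify <<- pa
    res$classSummaries <<- classSummaries(pa, lnc)
    counts_rows$classify <<- c(n_lnc = nrow(pa),
                               n_classified = sum(pa$class != "unclassified"))
    wtsv(pa, "classification.tsv")
  })

  run_stage("quantify", function() {
    lens <- txLengths(ann)
    se <- computeRpkm(study$counts, lens[rownames(study$counts)])
    sets <- expressedSets(se, threshold = config$rpkmCutoff)
    venn <- vennPartition(sets)
    res$rpkm <<- se
    res$expressedSets <<- sets
    res$venn <<- venn
    if (!is.null(res$classify))   # add per-tissue class proportions
      res$classSummaries <<- classSummaries(res$classify,
                                            ann[lnc_ids()], expressed = sets)
    counts_rows$quantify <<- c(
      n_features = nrow(se),
      stats::setNames(vapply(sets, length, integer(1)),
                      paste0("expressed_", names(sets))))
    rp <- as.data.frame(SummarizedExperiment::assay(se, "rpkm"))
    wtsv(cbind(feature_id = rownames(rp), rp), "rpkm.tsv")
    wtsv(data.frame(region = names(venn$counts), n = unname(venn$counts)),
         "venn_regions.tsv")
  })

  run_stage("de", function() {
    expressed <- unique(unlist(res$expressedSets))
    se <- study$counts[rownames(study$counts) %in% expressed, ]
    de <- do.call(rbind, lapply(contrasts, function(ct)
      deTest(se, ct, stat = config$deStat,
             fcCutoff = config$fcCutoff, qCutoff = config$qCutoff)))
    mir_tissue <- sub("_[^_]+$", "", colnames(study$mirExpression))
    de_mir <- do.call(rbind, lapply(contrasts, function(ct)
      deTest(study$mirExpression, ct, tissue = mir_tissue,
             stat = config$deStat, fcCutoff = config$fcCutoff,
             qCutoff = config$qCutoff)))
    res$de <<- de
    res$deMir <<- de_mir
    counts_rows$de <<- c(n_tested = nrow(de),
                         n_significant = sum(de$significant),
                         n_mir_significant = sum(de_mir$significant))
    wtsv(de, "de_results.tsv")
    wtsv(de_mir, "de_mirna.tsv")
  })

  run_stage("cis", function() {
    sig <- res$de[res$de$significant, ]
    is_lnc <- sig$feature_id %in% lnc_ids()
    deLnc <- unique(sig$feature_id[is_lnc])
    deGenes <- unique(sig$feature_id[!is_lnc])
    spans <- txSpans(ann)
    cis <- predictCisTargets(
      deLnc, deGenes,
      SummarizedExperiment::assay(res$rpkm, "rpkm"),
      spans[names(spans) %in% deLnc],
      spans[names(spans) %in% deGenes],
      window = config$cisWindow, alpha = config$cisAlpha)
    res$cis <<- cis
    counts_rows$cis <<- c(n_de_lnc = length(deLnc),
                          n_cis_pairs = nrow(cis))
    wtsv(cis, "cis_targets.tsv")
  })

  run_stage("enrich", function() {
    targets <- unique(res$cis$gene_id)
    background <- unique(study$termMap$gene_id)
    enr <- enrichTerms(study$termMap, intersect(targets, background),
                       background)
    res$enrich <<- enr
    counts_rows$enrich <<- c(n_terms = nrow(enr),
                             n_q05 = sum(enr$q <= 0.05))
    wtsv(enr, "enrichment.tsv")
  })

  run_stage("cerna", function() {
    trends <- buildTrends(rbind(res$de, res$deMir))
    net <- buildCernaNetwork(study$mirTargetsLnc, study$mirTargetsMrna,
                             trends)
    res$trends <<- trends
    res$cerna <<- net
    counts_rows$cerna <<- c(n_candidates = nrow(net),
                            n_accepted = sum(net$accepted),
                            n_skipped = attr(net, "skipped"))
    wtsv(net, "cerna_triplets.tsv")
    exportNetwork(net, file.path(outdir, "cerna_network.sif"),
                  file.path(outdir, "cerna_nodes.tsv"))
  })

  cfg <- config; class(cfg) <- NULL
  cfg_path <- file.path(outdir, "pipeline_config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("lncflow")),
    stages = config$stages,
    row_counts = lapply(counts_rows, as.list))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
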