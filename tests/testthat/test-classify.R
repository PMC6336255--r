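# Span coordinates are 1-based closed: the half-open span [1000, 2000) on
# the forward strand is written gr1(chrom, 1001, 2000, "+") here.

test_that("the six positional classes match their definitions", {
  expect_equal(classifyPosition(gr1("c", 1001, 2000, "+"),
                                gr1("c", 501, 3000, "+")), "nested")
  expect_equal(classifyPosition(gr1("c", 501, 3000, "+"),
                                gr1("c", 1001, 2000, "+")), "containing")
  expect_equal(classifyPosition(gr1("c", 101, 600, "+"),
                                gr1("c", 401, 900, "+")), "overlapping")
  expect_equal(classifyPosition(gr1("c", 101, 500, "+"),
                                gr1("c", 1001, 1500, "+")), "same_strand")
  expect_equal(classifyPosition(gr1("c", 101, 500, "+"),
                                gr1("c", 1001, 1500, "-")), "convergent")
  expect_equal(classifyPosition(gr1("c", 1001, 1500, "+"),
                                gr1("c", 101, 500, "-")), "divergent")
})

test_that("degenerate geometries classify deterministically", {
  # identical spans: containment read inclusively, resolved as containing
  expect_equal(classifyPosition(gr1("c", 100, 500, "+"),
                                gr1("c", 100, 500, "-")), "containing")
  # genic subtype ignores strand
  expect_equal(classifyPosition(gr1("c", 501, 3000, "-"),
                                gr1("c", 1001, 2000, "+")), "containing")
  # adjacency has no shared base: intergenic
  expect_equal(classifyPosition(gr1("c", 101, 200, "+"),
                                gr1("c", 201, 300, "+")), "same_strand")
  expect_error(classifyPosition(gr1("c1", 1, 10, "+"),
                                gr1("c2", 1, 10, "+")), "chromosome")
  expect_error(classifyPosition(gr1("c", 1, 10, "*"),
                                gr1("c", 20, 30, "+")), "strand")
})

test_that("classifier agrees with the brute-force oracle and partitions all cases", {
  set.seed(5)
  n <- 1000
  ls <- sample(5000, n, replace = TRUE); lw <- sample(2000, n, replace = TRUE)
  ps <- sample(5000, n, replace = TRUE); pw <- sample(2000, n, replace = TRUE)
  lstr <- sample(c("+", "-"), n, replace = TRUE)
  pstr <- sample(c("+", "-"), n, replace = TRUE)
  got <- classifyPosition(gr1("c", ls, ls + lw, lstr),
                          gr1("c", ps, ps + pw, pstr))
  want <- vapply(seq_len(n), function(i)
    bruteClassify(ls[i], ls[i] + lw[i], lstr[i],
                  ps[i], ps[i] + pw[i], pstr[i]), character(1))
  expect_identical(got, want)
  expect_true(all(got %in% c("overlapping", "containing", "nested",
                             "same_strand", "convergent", "divergent")))
})

test_that("partner assignment prefers maximal overlap, then nearest gap", {
  lnc <- gr1("c", 1000, 2000, "+"); names(lnc) <- "L"
  genes <- c(gr1("c", 1700, 2600, "+"), gr1("c", 1950, 4000, "+"),
             gr1("c", 9000, 9500, "+"))
  names(genes) <- c("gBig", "gSmall", "gFar")
  pa <- assignPartners(lnc, genes)
  expect_equal(pa$partner_gene_id, "gBig")   # 301 bp beats 51 bp
  expect_equal(pa$overlap_bp, 301L)

  # no overlap: nearest gap within the window
  lnc2 <- gr1("c", 100000, 101000, "+"); names(lnc2) <- "L2"
  genes2 <- c(gr1("c", 110001, 111000, "+"), gr1("c", 150000, 151000, "+"))
  names(genes2) <- c("gNear", "gFarther")
  pa2 <- assignPartners(lnc2, genes2)
  expect_equal(pa2$partner_gene_id, "gNear")
  expect_equal(pa2$gap_bp, 9000)

  # nothing within maxGap: unclassified
  pa3 <- assignPartners(lnc2, genes2, maxGap = 5000)
  expect_equal(pa3$class, "unclassified")
  expect_true(is.na(pa3$partner_gene_id))
  expect_identical(pa3$gap_bp, Inf)
})

test_that("equidistant flanking genes break ties toward the smaller start", {
  lnc <- gr1("c", 10000, 11000, "+"); names(lnc) <- "L"
  flank <- c(gr1("c", 12001, 13000, "+"), gr1("c", 8000, 8999, "+"))
  names(flank) <- c("gRight", "gLeft")
  # both gaps are 1000; exhaustive enumeration of the two candidates
  # leaves the smaller start (gLeft at 8000) as the deterministic choice
  expect_equal(gapDistance(lnc, flank["gRight"]),
               gapDistance(lnc, flank["gLeft"]))
  expect_equal(assignPartners(lnc, flank)$partner_gene_id, "gLeft")
})

test_that("planted classes in the synthetic study are recovered exactly", {
  st <- simulateStudy(simulationConfig(seed = 4, nbDispersion = 0.1))
  ann <- st$annotation
  cat_ <- txCategory(ann)
  lnc <- ann[transcriptIds(ann)[cat_ == "known_lncRNA" |
    (cat_ == "assembled" & !grepl("^DEC", transcriptIds(ann)))]]
  genes <- ann[transcriptIds(ann)[cat_ == "known_coding"]]
  pa <- assignPartners(lnc, genes)
  truth <- st$truth[!is.na(st$truth$class), ]
  m <- merge(truth, pa, by.x = "feature_id", by.y = "lnc_id")
  expect_equal(nrow(m), nrow(truth))
  expect_identical(m$class.y, m$class.x)
})

test_that("class summaries conserve totals and proportions", {
  set.seed(9)
  # 60 lncRNAs, 10 per class, planted geometrically via the generator
  st <- simulateStudy(simulationConfig(seed = 2, nLncPerClass = 10,
                                       nCodingGenes = 70))
  ann <- st$annotation
  cat_ <- txCategory(ann)
  lnc <- ann[st$truth$feature_id[!is.na(st$truth$class)]]
  genes <- ann[transcriptIds(ann)[cat_ == "known_coding"]]
  pa <- assignPartners(lnc, genes)
  sm <- classSummaries(pa, lnc)
  expect_equal(sm$class_counts$n, rep(10L, 6))
  expect_equal(sm$class_counts$proportion, rep(1 / 6, 6))
  # conservation: length bins and chromosome density tally all classified
  expect_equal(sum(sm$length_bins$Freq), 60)
  expect_equal(sum(sm$chrom_density$Freq), 60)
  # empty input gives empty tables
  empty <- classSummaries(pa[0, ], lnc)
  expect_equal(nrow(empty$class_counts), 0)
  # per-tissue proportions sum to 1 within each tissue with members
  sets <- list(flower = pa$lnc_id[1:30], leaf = pa$lnc_id[11:60])
  sm2 <- classSummaries(pa, lnc, expressed = sets)
  agg <- tapply(sm2$class_by_tissue$proportion, sm2$class_by_tissue$tissue, sum)
  expect_equal(as.numeric(agg[c("flower", "leaf")]), c(1, 1))
})
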