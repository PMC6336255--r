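.trendDf <- function(...) {
  rows <- list(...)
  df <- data.frame(feature_id = names(rows))
  m <- do.call(rbind, rows)
  colnames(m) <- c("flower-vs-leaf", "flower-vs-root", "leaf-vs-root")
  cbind(df, as.data.frame(m, check.names = FALSE))
}

test_that("trend profiles condense DE tables into signed vectors", {
  de <- rbind(
    data.frame(feature_id = "f1", contrast = "flower-vs-leaf",
               log2fc = 2.0, significant = TRUE),
    data.frame(feature_id = "f1", contrast = "flower-vs-root",
               log2fc = 1.5, significant = TRUE),
    data.frame(feature_id = "f1", contrast = "leaf-vs-root",
               log2fc = 0.2, significant = FALSE),
    data.frame(feature_id = "f2", contrast = "flower-vs-leaf",
               log2fc = -0.1, significant = FALSE),
    data.frame(feature_id = "f2", contrast = "flower-vs-root",
               log2fc = 0.3, significant = FALSE),
    data.frame(feature_id = "f2", contrast = "leaf-vs-root",
               log2fc = -1.8, significant = TRUE))
  tr <- buildTrends(de)
  expect_equal(unlist(tr[tr$feature_id == "f1", -1]),
               c("flower-vs-leaf" = 1L, "flower-vs-root" = 1L,
                 "leaf-vs-root" = 0L))
  expect_equal(unname(unlist(tr[tr$feature_id == "f2", -1])), c(0L, 0L, -1L))
  # row-by-row oracle over the whole table
  for (i in seq_len(nrow(de))) {
    want <- if (de$significant[i]) sign(de$log2fc[i]) else 0L
    expect_equal(tr[tr$feature_id == de$feature_id[i], de$contrast[i]],
                 as.integer(want))
  }
  expect_error(buildTrends(de[de$contrast != "leaf-vs-root", ],
                           contrasts = unique(de$contrast)), "leaf-vs-root")
})

test_that("the ceRNA trend rule accepts opposite-miRNA and rejects concordant-miRNA triplets", {
  trends <- .trendDf(lnc1 = c(1, 1, 0), mrna1 = c(1, 1, 0),
                     mirGood = c(-1, -1, 0), mirBad = c(1, 1, 0),
                     mirNull = c(0, 0, 0))
  lncT <- data.frame(mirna_id = c("mirGood", "mirBad", "mirNull"),
                     target_id = "lnc1")
  mrnaT <- data.frame(mirna_id = c("mirGood", "mirBad", "mirNull"),
                      target_id = "mrna1")
  net <- buildCernaNetwork(lncT, mrnaT, trends)
  expect_equal(nrow(net), 3)
  expect_true(net$accepted[net$mirna_id == "mirGood"])
  expect_false(net$accepted[net$mirna_id == "mirBad"])
  expect_false(net$accepted[net$mirna_id == "mirNull"])
  expect_equal(net$shared_contrasts[net$mirna_id == "mirGood"],
               "flower-vs-leaf,flower-vs-root")
  # no shared miRNA between the tables: no triplet at all
  net2 <- buildCernaNetwork(
    data.frame(mirna_id = "mirA", target_id = "lnc1"),
    data.frame(mirna_id = "mirB", target_id = "mrna1"), trends)
  expect_equal(nrow(net2), 0)
})

test_that("global sign flip leaves the accepted set unchanged", {
  trends <- .trendDf(lnc1 = c(1, 0, -1), mrna1 = c(1, 0, -1),
                     mrna2 = c(-1, 0, 1), mir1 = c(-1, 0, 1))
  lncT <- data.frame(mirna_id = "mir1", target_id = "lnc1")
  mrnaT <- data.frame(mirna_id = "mir1", target_id = c("mrna1", "mrna2"))
  net <- buildCernaNetwork(lncT, mrnaT, trends)
  flipped <- trends
  flipped[, -1] <- -flipped[, -1]
  net_f <- buildCernaNetwork(lncT, mrnaT, flipped)
  expect_identical(net$accepted, net_f$accepted)
})

test_that("network builder equals brute-force triple enumeration on random instances", {
  set.seed(61)
  for (trial in 1:15) {
    lncs <- paste0("l", 1:5); mirs <- paste0("m", 1:3); mrnas <- paste0("r", 1:5)
    feats <- c(lncs, mirs, mrnas)
    tm <- matrix(sample(c(-1L, 0L, 1L), length(feats) * 3, replace = TRUE),
                 ncol = 3)
    trends <- data.frame(feature_id = feats)
    colnames(tm) <- c("flower-vs-leaf", "flower-vs-root", "leaf-vs-root")
    trends <- cbind(trends, as.data.frame(tm, check.names = FALSE))
    lncT <- unique(data.frame(
      mirna_id = sample(mirs, 8, replace = TRUE),
      target_id = sample(lncs, 8, replace = TRUE)))
    mrnaT <- unique(data.frame(
      mirna_id = sample(mirs, 8, replace = TRUE),
      target_id = sample(mrnas, 8, replace = TRUE)))
    got <- buildCernaNetwork(lncT, mrnaT, trends)
    want <- bruteTriplets(lncT, mrnaT, trends)
    key <- function(d) paste(d$lnc_id, d$mirna_id, d$mrna_id)
    expect_setequal(key(got), key(want))
    m <- match(key(want), key(got))
    expect_identical(got$accepted[m], want$accepted)
  }
})

test_that("features without trend profiles are skipped and counted", {
  trends <- .trendDf(lnc1 = c(1, 0, 0), mrna1 = c(1, 0, 0),
                     mir1 = c(-1, 0, 0))
  lncT <- data.frame(mirna_id = "mir1", target_id = c("lnc1", "lncMissing"))
  mrnaT <- data.frame(mirna_id = "mir1", target_id = "mrna1")
  net <- buildCernaNetwork(lncT, mrnaT, trends)
  expect_equal(attr(net, "skipped"), 1)
  expect_equal(net$lnc_id, "lnc1")
})

test_that("multi-predictor tables union by default and intersect on request", {
  trends <- .trendDf(lnc1 = c(1, 0, 0), mrna1 = c(1, 0, 0),
                     mir1 = c(-1, 0, 0), mir2 = c(-1, 0, 0))
  lncT <- data.frame(
    mirna_id = c("mir1", "mir1", "mir2"), target_id = "lnc1",
    source = c("psRNATarget", "psRobot", "psRNATarget"))
  mrnaT <- data.frame(mirna_id = c("mir1", "mir2"), target_id = "mrna1",
                      source = "miranda")
  net_u <- buildCernaNetwork(lncT, mrnaT, trends)
  expect_equal(nrow(net_u), 2)
  net_i <- buildCernaNetwork(lncT, mrnaT, trends, combine = "intersection")
  expect_equal(net_i$mirna_id, "mir1")  # mir2-lnc1 seen by one source only
})

test_that("SIF export deduplicates edges and is byte-stable", {
  triplets <- data.frame(
    lnc_id = c("l1", "l2"), mirna_id = c("m1", "m1"),
    mrna_id = c("r1", "r1"), shared_contrasts = "flower-vs-leaf",
    accepted = TRUE)
  sif <- withr::local_tempfile(fileext = ".sif")
  nodes <- withr::local_tempfile(fileext = ".tsv")
  out <- exportNetwork(triplets, sif, nodes)
  # 2 lnc edges + 1 deduplicated mrna edge
  expect_equal(nrow(out$edges), 3)
  expect_equal(readLines(sif),
               c("m1\ttargets\tl1", "m1\ttargets\tl2", "m1\ttargets\tr1"))
  nd <- read.delim(nodes)
  expect_equal(nd$id[nd$type == "miRNA"], "m1")
  expect_setequal(nd$id[nd$type == "lncRNA"], c("l1", "l2"))
  # one accepted triplet yields exactly two edges
  one <- exportNetwork(triplets[1, ], sif, nodes)
  expect_equal(nrow(one$edges), 2)
  # re-export is byte-identical
  h1 <- tools::md5sum(sif)
  exportNetwork(triplets[1, ], sif, nodes)
  expect_identical(unname(tools::md5sum(sif)), unname(h1))
})
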