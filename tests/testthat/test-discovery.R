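.mkTx <- function(ids, lengths) {
  # single-exon transcripts far apart on one chromosome
  df <- do.call(rbind, lapply(seq_along(ids), function(i) data.frame(
    chrom = "chr1", start = 1 + (i - 1) * 10000,
    end = (i - 1) * 10000 + lengths[i], strand = "+",
    transcript_id = ids[i], gene_id = ids[i], category = "assembled")))
  makeTranscriptSet(df)
}

.mkEv <- function(ids, cpc = -1, pfam = 0, cov = 5, ident = 50, ovl = 0) {
  data.frame(transcript_id = ids, cpc_score = cpc, pfam_hit = pfam,
             read_coverage = cov, known_lnc_identity = ident,
             overlaps_known_coding = ovl)
}

test_that("filter cascade attributes the first violated step", {
  ids <- paste0("t", 1:6)
  ts <- .mkTx(ids, c(150, 300, 300, 300, 300, 300))
  ev <- .mkEv(ids)
  ev$read_coverage[2] <- 2
  ev$overlaps_known_coding[3] <- 1
  ev$known_lnc_identity[4] <- 95
  ev$pfam_hit[5] <- 1
  # t6 passes everything
  out <- runFilterCascade(ts, ev)
  expect_equal(out$failed_step,
               c("length", "coverage", "known_overlap",
                 "known_lnc_similarity", "coding_potential", "none"))
  expect_identical(out$passed, out$failed_step == "none")
  # a short transcript failing later steps too is attributed to length
  ev2 <- .mkEv(ids); ev2$read_coverage[1] <- 0.5; ev2$cpc_score[1] <- 2
  expect_equal(runFilterCascade(ts, ev2)$failed_step[1], "length")
})

test_that("boundary semantics follow the printed inequalities literally", {
  ids <- paste0("b", 1:4)
  ts <- .mkTx(ids, c(200, 300, 300, 300))
  ev <- .mkEv(ids)
  ev$read_coverage[2] <- 3        # exactly 3: kept
  ev$known_lnc_identity[3] <- 90  # exactly 90%: kept
  ev$cpc_score[4] <- 0            # exactly 0: removed (< 0 required)
  out <- runFilterCascade(ts, ev)
  expect_equal(out$failed_step, c("none", "none", "none", "coding_potential"))
})

test_that("missing-identity transcripts are not removed for similarity", {
  ts <- .mkTx("t1", 300)
  ev <- .mkEv("t1"); ev$known_lnc_identity <- NA
  expect_true(runFilterCascade(ts, ev)$passed)
})

test_that("cascade validates its inputs", {
  ts <- .mkTx(c("t1", "t2"), c(300, 300))
  expect_error(runFilterCascade(ts, .mkEv("t1")), "t2")
  ev <- .mkEv(c("t1", "t2")); ev$read_coverage[1] <- -2
  expect_error(runFilterCascade(ts, ev), "negative")
})

test_that("cascade is order-invariant and survivors are the intersection of per-step pass sets", {
  set.seed(3)
  ids <- sprintf("r%03d", 1:80)
  lens <- sample(c(120, 200, 400, 900), 80, replace = TRUE)
  ts <- .mkTx(ids, lens)
  ev <- data.frame(
    transcript_id = ids,
    cpc_score = round(runif(80, -2, 2), 2),
    pfam_hit = rbinom(80, 1, 0.3),
    read_coverage = round(runif(80, 0, 10), 1),
    known_lnc_identity = round(runif(80, 0, 100), 1),
    overlaps_known_coding = rbinom(80, 1, 0.2))
  out <- runFilterCascade(ts, ev)
  # order invariance
  perm <- sample(80)
  out_perm <- runFilterCascade(ts[ids[perm]], ev)
  expect_identical(out_perm[match(ids, out_perm$transcript_id), "failed_step"],
                   out$failed_step)
  # survivors = intersection of the per-step pass sets
  pass_sets <- list(
    ids[lens >= 200],
    ids[ev$read_coverage >= 3],
    ids[ev$overlaps_known_coding == 0],
    ids[is.na(ev$known_lnc_identity) | ev$known_lnc_identity <= 90],
    ids[ev$cpc_score < 0 & ev$pfam_hit == 0])
  expect_setequal(out$transcript_id[out$passed], Reduce(intersect, pass_sets))
  # relaxing any one threshold never shrinks the survivor set
  base_n <- sum(out$passed)
  expect_gte(sum(runFilterCascade(ts, ev, minLength = 100)$passed), base_n)
  expect_gte(sum(runFilterCascade(ts, ev, minCoverage = 1)$passed), base_n)
  expect_gte(sum(runFilterCascade(ts, ev, maxKnownIdentity = 99)$passed), base_n)
  expect_gte(sum(runFilterCascade(ts, ev, cpcCutoff = 1)$passed), base_n)
})

test_that("deduplication collapses identical exon structures only", {
  df <- data.frame(
    chrom = "chr1",
    start = c(101, 301, 101, 301, 101, 302),
    end = c(200, 500, 200, 500, 200, 500),
    strand = "+",
    transcript_id = rep(c("a", "b", "c"), each = 2),
    gene_id = rep(c("ga", "gb", "gc"), each = 2))
  dd <- deduplicateTranscripts(makeTranscriptSet(df))
  # a and b identical -> first id kept; c differs by 1 bp -> kept
  expect_identical(transcriptIds(dd), c("a", "c"))
  empty <- makeTranscriptSet(df)[character(0)]
  expect_equal(length(deduplicateTranscripts(empty)), 0)
})

test_that("longest ORF matches closed forms and the exhaustive scan", {
  expect_equal(findLongestOrf("ATGAAATAG"), 9L)
  expect_equal(findLongestOrf("CCCCCC"), 0L)
  expect_equal(findLongestOrf("ATGTAG"), 6L)
  # start without stop, and stop without start
  expect_equal(findLongestOrf("ATGAAAAAA"), 0L)
  expect_equal(findLongestOrf("TAGTAATGA"), 0L)
  expect_error(findLongestOrf("ATGXXX"), "outside")
  set.seed(11)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    expect_equal(findLongestOrf(s), bruteOrf(s), info = s)
  }
})

test_that("characterization table reports length, exons and per-row ORF", {
  df <- data.frame(chrom = "chr1", start = c(101, 301, 1001),
                   end = c(200, 450, 1600), strand = "+",
                   transcript_id = c("t1", "t1", "t2"),
                   gene_id = c("g1", "g1", "g2"))
  ts <- makeTranscriptSet(df)
  seqs <- Biostrings::DNAStringSet(c(
    t1 = paste(rep("C", 250), collapse = ""),
    t2 = paste0("ATGAAATAG", paste(rep("C", 591), collapse = ""))))
  ch <- characterizeTranscripts(ts, seqs)
  expect_equal(ch$length, c(250, 600))
  expect_equal(ch$n_exons, c(2, 1))
  expect_equal(ch$orf_length, unname(findLongestOrf(seqs)))
})
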