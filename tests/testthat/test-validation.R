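# Secretion-signal heuristic, chi-square enrichment, E-value binning and
# comparison, domain overlaps, BLAST tabular reduction.

test_that("the signal heuristic applies the three-region model", {
  # charged n-region, hydrophobic core, A-S-A cleavage motif: positive,
  # mature protein starting right after the motif (position 16)
  pos <- paste0("MK", strrep("L", 10), "ASA", strrep("Q", 20))
  p <- predictSignal(c(sig = pos))
  expect_true(p$call)
  expect_identical(p$cleavage_position, 16L)

  # acidic N-terminus: no hydrophobic core, negative
  neg <- paste0("M", strrep("D", 20), strrep("L", 20))
  expect_false(predictSignal(c(x = neg))$call)

  # shorter than 15 residues: degenerate, negative
  expect_false(predictSignal(c(s = "MKLLLLLLLL"))$call)

  # call implies cleavage position; no call implies NA
  both <- predictSignal(c(a = pos, b = neg))
  expect_identical(is.na(both$cleavage_position), !both$call)
})

test_that("the heuristic recovers planted signal rates on generated proteins", {
  cfg <- scenarioConfig(seed = 6, nBodyGenes = 300, nVenomGenes = 40,
                        nArtifactContigs = 10, nGoTerms = 5)
  sc <- simulateScenario(cfg)
  genes <- names(sc@truth$label)[sc@truth$label != "artifact"]
  lo <- longestOrf(sc@transcripts[genes])
  preds <- predictSignal(setNames(lo$sequence, lo$transcript_id))
  sig <- sc@truth$signal
  m <- merge(preds, sig, by.x = "protein_id", by.y = "transcript_id")
  # every planted motif is detected, at the planted cleavage site
  expect_true(all(m$call[m$planted]))
  expect_identical(m$cleavage_position.x[m$planted],
                   m$cleavage_position.y[m$planted])
  # measured class rates fall in the binomial 95% CI of the planting rates
  lab <- sc@truth$label[m$protein_id]
  kv <- sum(m$call[lab == "venom"]); kb <- sum(m$call[lab == "body"])
  expect_true(kv >= qbinom(0.025, 40, 0.35) & kv <= qbinom(0.975, 40, 0.35))
  expect_true(kb >= qbinom(0.025, 300, 0.05) & kb <= qbinom(0.975, 300, 0.05))
})

test_that("external signal predictions can replace the heuristic", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tcall\tcleavage_position",
               "p1\tTRUE\t18", "p2\tFALSE\tNA"), f)
  ext <- readSignalPredictions(f)
  expect_identical(ext$call, c(TRUE, FALSE))
  expect_identical(ext$cleavage_position[1], 18L)
})

test_that("signal enrichment is a 2x2 chi-square without continuity correction", {
  # identical proportions: no association
  same <- signalEnrichment(10, 100, 10, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # all expected counts are 5: statistic = 4 * (10-5)^2/5 = 20
  hard <- signalEnrichment(10, 10, 0, 10)
  expect_equal(hard$statistic, 20)
  expect_equal(hard$df, 1)

  # symmetric in the two groups
  a <- signalEnrichment(39, 129, 1133, 21496)
  b <- signalEnrichment(1133, 21496, 39, 129)
  expect_equal(a$statistic, b$statistic)
  expect_lt(a$p_value, 1e-4)
  expect_identical(a$percent1, 30L)

  expect_error(signalEnrichment(0, 10, 0, 10), "zero marginal")
  expect_error(signalEnrichment(10, 10, 10, 10), "zero marginal")
})

test_that("E-value binning partitions values with edge-inclusive lower bins", {
  edges <- c(1e-100, 1e-50, 1e-10, 1e-3)
  d <- binEvalues(1e-60, edges)
  expect_identical(d$counts, c(0L, 1L, 0L, 0L, 0L))
  # a value exactly on an edge goes to the more significant bin
  expect_identical(binEvalues(1e-50, edges)$counts, c(0L, 1L, 0L, 0L, 0L))
  expect_identical(binEvalues(1e-100, edges)$counts, c(1L, 0L, 0L, 0L, 0L))
  expect_identical(binEvalues(numeric(0), edges)$counts, rep(0L, 5))
  expect_identical(binEvalues(0.5, edges)$counts, c(0L, 0L, 0L, 0L, 1L))
  expect_identical(binEvalues(1e-4, edges)$counts, c(0L, 0L, 0L, 1L, 0L))

  # conservation: bin counts always sum to the number of inputs
  set.seed(14)
  for (i in 1:20) {
    ev <- 10^runif(sample(1:50, 1), -120, 1)
    expect_identical(sum(binEvalues(ev)$counts), length(ev))
  }
})

test_that("distribution comparison collapses empty bins and scales correctly", {
  same <- compareEvalueDistributions(c(5, 9, 2), c(5, 9, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  hard <- compareEvalueDistributions(c(10, 0), c(0, 10))
  expect_equal(hard$statistic, 20)
  expect_equal(hard$df, 1)

  # zero-total bins are collapsed before computing df
  padded <- compareEvalueDistributions(c(10, 0, 0), c(0, 0, 10))
  expect_equal(padded$df, 1)

  # proportional scaling multiplies the statistic
  a <- c(12, 5, 3); b <- c(4, 9, 7)
  expect_equal(compareEvalueDistributions(10 * a, 10 * b)$statistic,
               10 * compareEvalueDistributions(a, b)$statistic)

  expect_error(compareEvalueDistributions(c(10, 0), c(10, 0)), "fewer than 2")
  expect_error(compareEvalueDistributions(c(1, 2), c(1, 2, 3)), "numbers of bins")
})

test_that("synthetic venom and body E-values differ significantly", {
  sc <- simulateScenario(tinyConfig(seed = 20))
  ev <- sc@evalues
  dv <- binEvalues(ev$evalue[ev$subset == "venom"], label = "venom")
  db_ <- binEvalues(ev$evalue[ev$subset == "body"], label = "body")
  cmp <- compareEvalueDistributions(dv, db_)
  expect_lt(cmp$p_value, 0.01)
})

test_that("domain overlap produces exclusive Venn regions", {
  v <- domainOverlap(c("a", "b"), c("b", "c"), c("b", "d"))
  expect_identical(unname(v[c("A_only", "B_only", "C_only")]), c(1L, 1L, 1L))
  expect_identical(unname(v["ABC"]), 1L)
  expect_identical(sum(v), 4L)  # |union|

  dis <- domainOverlap("x", "y", "z")
  expect_identical(unname(dis[c("AB_only", "AC_only", "BC_only", "ABC")]),
                   rep(0L, 4))

  eq <- domainOverlap(c("m", "n"), c("m", "n"), c("n", "m"))
  expect_identical(unname(eq["ABC"]), 2L)
  expect_identical(sum(eq), 2L)
})

test_that("BLAST tabular input reduces to the best hit per query", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("# comment",
            "q1\ts1\t90\t50\t2\t0\t1\t50\t1\t50\t1e-30\t120",
            "q1\ts2\t88\t50\t3\t0\t1\t50\t1\t50\t1e-45\t150",
            "q2\ts3\t99\t40\t0\t0\t1\t40\t1\t40\t1e-10\t80",
            "q2\ts4\t95\t40\t1\t0\t1\t40\t1\t40\t1e-10\t95")
  writeLines(rows, f)
  hits <- readBlastTab(f)
  expect_identical(nrow(hits), 4L)
  best <- bestHitPerQuery(hits)
  expect_identical(best$sseqid[best$qseqid == "q1"], "s2")   # lowest E
  expect_identical(best$sseqid[best$qseqid == "q2"], "s4")   # tie: bitscore
})
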