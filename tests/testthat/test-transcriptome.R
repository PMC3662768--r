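# FASTA ingestion, assembly statistics, TPM quantification (closed form and
# EM), and the expression filter.

writeFasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("readTranscripts ingests, normalizes and validates", {
  f <- writeFasta(c(">t1 some description", "acgtacgt", ">t2", "GGGCCC"))
  tx <- readTranscripts(f)
  expect_identical(transcriptIds(tx), c("t1", "t2"))
  expect_identical(as.character(sequences(tx)[["t1"]]), "ACGTACGT")
  expect_identical(unname(transcriptLengths(tx)), c(8L, 6L))

  expect_error(readTranscripts(writeFasta(c(">a", "ACGT", ">a", "GGGG"))),
               "duplicate")
  expect_error(readTranscripts(writeFasta(c(">a", "", ">b", "ACGT"))),
               "empty")
})

test_that("assembly statistics match the worked example", {
  st <- assemblyStats(c(700, 500, 300, 300, 200, 200, 200))
  expect_identical(st$n50, 500)
  expect_equal(st$mean_length, 2400 / 7, tolerance = 1e-12)
  expect_identical(st$n_transcripts, 7L)

  expect_identical(assemblyStats(500)$n50, 500)
  expect_identical(assemblyStats(rep(42, 9))$n50, 42)
  expect_identical(assemblyStats(numeric(0)),
                   data.frame(n_transcripts = 0L, n50 = 0, mean_length = 0))
  # the >100 bp count is strict
  expect_identical(assemblyStats(c(100, 101, 500))$n_transcripts, 2L)
})

test_that("n50 agrees with a brute-force oracle on 1000 random length sets", {
  set.seed(99)
  for (i in seq_len(1000)) {
    lens <- sample(50:5000, sample(1:40, 1), replace = TRUE)
    expect_equal(n50(lens), as.numeric(bruteN50(lens)))
  }
})

test_that("TPM follows the length-normalized rate formula", {
  tx <- TranscriptomeSet(c(a = randomNtString(1000), b = randomNtString(2000)))
  tx <- estimateTpm(tx, c(a = 10, b = 10))
  expect_equal(unname(tpm(tx)), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  one <- estimateTpm(TranscriptomeSet(c(x = randomNtString(300))),
                     c(x = 7))
  expect_equal(unname(tpm(one)), 1e6)

  zero <- estimateTpm(tx, c(a = 0, b = 0))
  expect_identical(unname(tpm(zero)), c(0, 0))

  expect_error(estimateTpm(tx, c(zzz = 5)), "unknown transcript")
})

test_that("EM splits ambiguous counts by abundance and matches closed forms", {
  tx <- TranscriptomeSet(c(a = randomNtString(500), b = randomNtString(500)))
  # symmetric: one shared group, no unique counts -> 5/5 split
  counts <- data.frame(transcript_id = c("a", "b"), length_bp = 500,
                       count = c(10, 10), ambiguity_group = "g1")
  q <- estimateTpm(tx, counts)
  expect_equal(unname(readCounts(q)), c(5, 5))
  expect_equal(unname(tpm(q)), c(5e5, 5e5))

  # asymmetric fixed point, solved by hand: unique 30 and 10 plus a shared
  # group of 20 on equal lengths -> a1 = 30 + 20 a1/60 => a1 = 45, a2 = 15
  counts2 <- data.frame(transcript_id = c("a", "b", "a", "b"),
                        length_bp = 500,
                        count = c(30, 10, 20, 20),
                        ambiguity_group = c(NA, NA, "g1", "g1"))
  q2 <- estimateTpm(tx, counts2)
  expect_equal(unname(readCounts(q2)), c(45, 15), tolerance = 1e-6)

  # EM with no ambiguity equals the closed-form rate formula exactly
  set.seed(4)
  tx3 <- TranscriptomeSet(setNames(
    vapply(sample(200:2000, 8), randomNtString, character(1)),
    paste0("t", 1:8)))
  cnt <- setNames(sample(0:500, 8), paste0("t", 1:8))
  q3 <- estimateTpm(tx3, cnt)
  rate <- cnt / transcriptLengths(tx3)
  expect_equal(unname(tpm(q3)), unname(rate / sum(rate) * 1e6),
               tolerance = 1e-12)
})

test_that("TPM sums to one million whenever any count is positive", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    tx <- TranscriptomeSet(setNames(
      vapply(sample(100:3000, n, replace = TRUE), randomNtString,
             character(1)), paste0("t", seq_len(n))))
    cnt <- setNames(rpois(n, 40), paste0("t", seq_len(n)))
    if (sum(cnt) == 0) cnt[1] <- 1
    q <- estimateTpm(tx, cnt)
    expect_equal(sum(tpm(q)), 1e6, tolerance = 1e-3)
  }
})

test_that("the expression filter is an inclusive, exhaustive partition", {
  tx <- TranscriptomeSet(setNames(
    vapply(c(300, 400, 500), randomNtString, character(1)),
    c("lo", "mid", "hi")))
  tx@tpm <- c(0.5, 1.0, 3.2)
  flt <- filterExpressed(tx, 1)
  expect_identical(transcriptIds(flt$kept), c("mid", "hi"))
  expect_identical(transcriptIds(flt$removed), "lo")
  expect_identical(sort(c(transcriptIds(flt$kept),
                          transcriptIds(flt$removed))),
                   sort(transcriptIds(tx)))

  all_kept <- filterExpressed(tx, 0)
  expect_identical(all_kept$n_kept, 3L)

  expect_identical(flt$retained_percent, reportPercent(2, 3))
  expect_error(filterExpressed(TranscriptomeSet(c(a = "ACGT"))), "tpm")
})

test_that("count tables round-trip through TSV", {
  counts <- data.frame(transcript_id = c("a", "b"), length_bp = c(100L, 200L),
                       count = c(5, 10), ambiguity_group = c(NA, "g1"),
                       stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(counts, f)
  back <- readCountTable(f)
  expect_identical(back$transcript_id, counts$transcript_id)
  expect_identical(back$ambiguity_group, c(NA, "g1"))
})
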