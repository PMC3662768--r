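# Peptide filter cascade, mapping with I/L equivalence, razor protein
# inference, coverage and spectral summaries.

pepRow <- function(sequence, probability = 0.9, charge = 2L,
                   spectral_count = 1L) {
  data.frame(sequence = sequence, probability = probability, charge = charge,
             spectral_count = spectral_count, stringsAsFactors = FALSE)
}

dbFor <- function(proteins) {
  tx <- TranscriptomeSet(setNames(
    vapply(proteins, codingDna, character(1)), names(proteins)))
  buildSearchDatabase(tx, minAaLen = 5)
}

test_that("the filter cascade applies strict thresholds and charge exclusion", {
  obs <- rbind(pepRow("AAAA", 0.9, 2),    # length 4: removed (>4 strict)
               pepRow("AAAAAAAAAA", 0.5, 2),  # probability 0.5: removed
               pepRow("AAAAAAAAAA", 0.9, 1),  # +1 charge: removed
               pepRow("AAAAA", 0.51, 2))      # all strict thresholds met
  kept <- filterPeptides(obs)
  expect_identical(kept$sequence, "AAAAA")
  expect_identical(nrow(attr(kept, "removed")), 3L)
})

test_that("the peptide filter is idempotent", {
  set.seed(8)
  obs <- pepRow(vapply(sample(3:12, 60, TRUE), randomProteinString,
                       character(1)),
                probability = runif(60), charge = sample(1:3, 60, TRUE))
  once <- filterPeptides(obs)
  twice <- filterPeptides(once)
  attr(once, "removed") <- NULL
  attr(twice, "removed") <- NULL
  expect_identical(once, twice)
})

test_that("peptides map by exact substring with I/L equivalence", {
  db <- dbFor(c(tx1 = "MGGSAKWAAAA"))
  m <- mapPeptides(pepRow("GGSAK"), db)
  expect_identical(nrow(m$matches), 1L)
  expect_identical(m$matches$aa_start, 1L)
  expect_identical(m$matches$transcript_id, "tx1")
  expect_true(m$matches$unique_flag)

  # I/L equivalence: GISAK finds GLSAK
  db2 <- dbFor(c(tx1 = "MWGLSAKWAAA"))
  m2 <- mapPeptides(pepRow("GISAK"), db2)
  expect_identical(nrow(m2$matches), 1L)
  m2off <- mapPeptides(pepRow("GISAK"), db2, collapseIl = FALSE)
  expect_identical(nrow(m2off$matches), 0L)
  expect_identical(m2off$unmatched, "GISAK")

  # a peptide matching two transcripts is flagged non-unique
  db3 <- dbFor(c(a = "MGGSAKWAAAA", b = "MQGGSAKWQQQ"))
  m3 <- mapPeptides(pepRow("GGSAK"), db3)
  expect_identical(nrow(m3$matches), 2L)
  expect_false(any(m3$matches$unique_flag))

  # multiple placements within one transcript still count one transcript hit
  db4 <- dbFor(c(a = "MGGSAKWGGSAKW"))
  m4 <- mapPeptides(pepRow("GGSAK"), db4)
  expect_identical(nrow(m4$matches), 2L)
  expect_true(all(m4$matches$unique_flag))
})

test_that("protein probability aggregates independent peptide evidence", {
  expect_equal(proteinProbability(c(0.9, 0.9)), 0.99)
  expect_equal(proteinProbability(0.4), 0.4)
  # monotone non-decreasing as peptides are added
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    extra <- runif(1)
    expect_gte(proteinProbability(c(p, extra)), proteinProbability(p))
  }
})

test_that("coverage merges overlapping intervals and is order-invariant", {
  expect_equal(peptideCoverage(c(10, 15), c(20, 30), 100), 0.20)
  expect_equal(peptideCoverage(0, 50, 50), 1.0)
  expect_equal(peptideCoverage(c(0, 50), c(5, 55), 100), 0.10)
  expect_equal(peptideCoverage(integer(0), integer(0), 10), 0)

  set.seed(10)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    s <- sample(0:80, n, replace = TRUE)
    e <- s + sample(1:15, n, replace = TRUE)
    base <- peptideCoverage(s, e, 100)
    o <- sample(n)
    expect_equal(peptideCoverage(s[o], e[o], 100), base)
    # monotone under adding a match
    expect_gte(peptideCoverage(c(s, 0), c(e, 8), 100), base)
  }
})

test_that("protein inference enforces the two-peptide and probability rules", {
  db <- dbFor(c(tx = "MGGSAKWQPLDKVVVNNWEK"))
  one <- pepRow("GGSAK", 0.99)
  m1 <- mapPeptides(one, db)
  expect_identical(nrow(inferProteins(m1, one, db)), 0L)

  two <- rbind(pepRow("GGSAK", 0.9), pepRow("WQPLDK", 0.9))
  m2 <- mapPeptides(two, db)
  ids <- inferProteins(m2, two, db)
  expect_identical(nrow(ids), 1L)
  expect_equal(ids$protein_probability, 0.99)
  expect_identical(ids$distinct_peptides, 2L)

  # two peptides whose joint probability stays below 0.7 are rejected
  weak <- rbind(pepRow("GGSAK", 0.55), pepRow("WQPLDK", 0.2))
  ids3 <- inferProteins(mapPeptides(weak, db), weak, db)
  expect_identical(nrow(ids3), 0L)
})

test_that("razor assignment credits shared peptides to the best transcript", {
  # transcript a has two unique peptides; b has none; the shared peptide
  # GGSAK occurs in both and must be credited to a
  db <- dbFor(c(a = "MGGSAKWQPLDKVVVNNWEK", b = "MQQGGSAKWDDDDDD"))
  obs <- rbind(pepRow("GGSAK", 0.9, spectral_count = 3),
               pepRow("WQPLDK", 0.9),
               pepRow("VVVNNWEK", 0.9))
  mp <- mapPeptides(obs, db)
  ids <- inferProteins(mp, obs, db)
  expect_identical(ids$transcript_id, "a")
  expect_identical(ids$distinct_peptides, 3L)
  asg <- attr(ids, "assignments")
  # conservation: every retained peptide assigned to exactly one transcript
  expect_identical(sort(names(asg)), sort(unique(ilCollapseTest(obs$sequence))))
  expect_identical(unname(asg["GGSAK"]), "a")
})

test_that("NSAF normalizes to one and retention mirrors printed percentages", {
  db <- dbFor(c(a = "MGGSAKWQPLDKVVVNNWEK", b = "MFFDERTTTPKYYYWWHHK"))
  obs <- rbind(pepRow("GGSAK", 0.9, spectral_count = 2),
               pepRow("WQPLDK", 0.9, spectral_count = 2),
               pepRow("FFDER", 0.9, spectral_count = 2),
               pepRow("TTTPK", 0.9, spectral_count = 2))
  ids <- inferProteins(mapPeptides(obs, db), obs, db)
  expect_identical(nrow(ids), 2L)
  expect_equal(sum(ids$nsaf), 1.0)
  # equal spectral counts on equal-length representative ORFs split evenly
  if (length(unique(ids$orf_length)) == 1L)
    expect_equal(ids$nsaf, c(0.5, 0.5))

  summ <- spectralSummary(ids, nInitialPeptides = 2917, nKeptPeptides = 2686)
  expect_identical(summ$retained_percent, 92L)
  expect_equal(summ$mean_distinct_peptides, 2)

  single <- spectralSummary(ids[1, , drop = FALSE])
  expect_identical(single$n_proteins, 1L)
  empty <- spectralSummary(ids[0, , drop = FALSE])
  expect_identical(empty$n_proteins, 0L)
})
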