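# Independent oracles and small fixture builders used across the suite.

# Naive codon-table translator: substring codons, standard code, '*' for
# stops, 'X' for any codon containing a non-ACGT character.
naiveTranslate <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3L
  if (n == 0) return("")
  codons <- substring(nt, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- ifelse(grepl("[^ACGT]", codons), "X", unname(gc[codons]))
  paste(aa, collapse = "")
}

naiveRevComp <- function(nt) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", nt), "")[[1]]), collapse = "")
}

# Brute-force N50: the largest length L present in the set such that
# transcripts of length >= L hold at least half the total bases.
bruteN50 <- function(lengths) {
  if (length(lengths) == 0) return(0)
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= half) return(L)
  min(lengths)
}

# Exhaustive hypergeometric upper tail P(X >= k) for population N, K carriers,
# draws n.
enumHyper <- function(k, K, N, n) {
  js <- max(0, k):min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Deterministic back-translation (first codon per residue) to build test
# transcripts coding for a chosen protein.
aa2nt <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  first <- vapply(split(names(gc), gc), `[`, character(1), 1L)
  res <- strsplit(aa, "")[[1]]
  paste(first[res], collapse = "")
}

# DNA coding a given protein in frame +1 with a trailing stop.
codingDna <- function(protein) paste0(aa2nt(protein), "TAA")

ilCollapseTest <- function(x) chartr("I", "L", x)

randomNtString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomProteinString <- function(n) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# Small, fast scenario for unit tests.
tinyConfig <- function(seed = 1L, ...) {
  scenarioConfig(seed = seed, nBodyGenes = 60L, nVenomGenes = 12L,
                 nArtifactContigs = 40L, nGoTerms = 10L,
                 nEnrichedTerms = 2L, totalReads = 2e5, ...)
}
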