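# Validation statistics: secretion-signal heuristic and enrichment, binned
# E-value distribution comparison, conserved-domain set overlap, BLAST
# tabular parsing.

SIGNAL_SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

# Heuristic secretion-signal call on one N-terminal sequence (character
# scalar). Rules (1-based residue positions):
#   (1) at least one K/R among residues 1-5 (positively charged n-region);
#   (2) an 8-residue window lying entirely within residues 6-25 whose mean
#       Kyte-Doolittle hydropathy is >= 1.5 (hydrophobic h-region);
#   (3) a cleavage position p in residues 15-35 (mature protein starts at p)
#       whose -3 and -1 residues (p-3 and p-1) are small ({A,G,S,C,T}),
#       the classical (-3,-1) rule.
# Sequences shorter than 15 residues are called FALSE. Residues outside the
# 20-letter alphabet (e.g. X) take hydropathy 0 and never satisfy rule (3).
.signalOne <- function(seq) {
  n <- nchar(seq)
  if (n < 15L)
    return(list(call = FALSE, score = NA_real_,
                cleavage_position = NA_integer_))
  res <- strsplit(substr(seq, 1L, 45L), "", fixed = TRUE)[[1]]
  kd <- unname(KYTE_DOOLITTLE[res])
  kd[is.na(kd)] <- 0
  charged <- any(res[1:5] %in% c("K", "R"))
  win_end <- min(25L, length(res))
  score <- NA_real_
  if (win_end - 6L + 1L >= 8L) {
    starts <- 6:(win_end - 7L)
    means <- vapply(starts, function(s) mean(kd[s:(s + 7L)]), numeric(1))
    score <- max(means)
  }
  hydrophobic <- !is.na(score) && score >= 1.5
  cleav <- NA_integer_
  for (p in 15:min(35L, length(res))) {
    if (res[p - 3L] %in% SIGNAL_SMALL_RESIDUES &&
        res[p - 1L] %in% SIGNAL_SMALL_RESIDUES) {
      cleav <- p
      break
    }
  }
  call <- charged && hydrophobic && !is.na(cleav)
  list(call = call, score = score,
       cleavage_position = if (call) cleav else NA_integer_)
}

#' Heuristic secretion-signal prediction
#'
#' A transparent stand-in for trained signal-peptide predictors, applying the
#' classical three-region model to the protein N-terminus: a charged
#' n-region (K/R among residues 1-5), a hydrophobic h-region (an 8-residue
#' window within residues 6-25 with mean Kyte-Doolittle hydropathy >= 1.5)
#' and a (-3,-1) small-residue cleavage site at a position in residues 15-35.
#' The call is the conjunction of the three rules; the cleavage position is
#' the first qualifying site (the mature protein starts there) and the score
#' is the best window hydropathy. Proteins shorter than 15 residues are
#' called negative. External predictions can be substituted via
#' \code{\link{readSignalPredictions}}.
#'
#' @param proteins Named character vector or \code{AAStringSet} of protein
#'   sequences (N-terminus first).
#' @return data.frame with \code{protein_id}, \code{call}, \code{score},
#'   \code{cleavage_position} (NA unless called).
#' @export
predictSignal <- function(proteins) {
  if (methods::is(proteins, "AAStringSet")) {
    ids <- names(proteins)
    proteins <- as.character(proteins)
  } else ids <- names(proteins)
  if (is.null(ids)) ids <- sprintf("protein%d", seq_along(proteins))
  res <- lapply(proteins, .signalOne)
  data.frame(protein_id = ids,
             call = vapply(res, `[[`, logical(1), "call"),
             score = vapply(res, `[[`, numeric(1), "score"),
             cleavage_position = vapply(res, `[[`, integer(1),
                                        "cleavage_position"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Import external signal-peptide predictions
#'
#' Accepts a TSV with columns \code{protein_id}, \code{call} (logical or
#' 0/1), and optional \code{cleavage_position}, so predictions from a trained
#' external tool can replace the built-in heuristic without code changes.
#'
#' @param file Path to the TSV.
#' @return data.frame with \code{protein_id}, \code{call},
#'   \code{cleavage_position}.
#' @export
readSignalPredictions <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("protein_id", "call") %in% names(df)))
    stop("signal prediction table must have protein_id and call columns",
         call. = FALSE)
  df$call <- as.logical(df$call)
  if (is.null(df$cleavage_position)) df$cleavage_position <- NA_integer_
  df[, c("protein_id", "call", "cleavage_position")]
}

#' Chi-square test of secretion-signal enrichment
#'
#' 2x2 chi-square test of independence (no continuity correction) comparing
#' the fraction of signal-positive proteins between two groups, e.g. venom
#' proteins versus body proteins.
#'
#' @param k1,n1 Signal-positive count and total for group 1 (venom).
#' @param k2,n2 Signal-positive count and total for group 2 (comparison).
#' @return list with \code{statistic}, \code{df}, \code{p_value}, and the two
#'   proportions as integer percentages (\code{percent1}, \code{percent2}).
#' @examples
#' signalEnrichment(39, 129, 1133, 21496)$p_value  # < 1e-4
#' @export
signalEnrichment <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("chi-square statistic undefined: zero marginal total", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       percent1 = reportPercent(k1, n1), percent2 = reportPercent(k2, n2))
}

#' Bin E-values on a descending powers-of-ten grid
#'
#' Assigns each E-value to exactly one bin. With edges
#' \code{e1 < e2 < ... < em} (ascending numeric value, i.e. descending
#' significance exponents) the bins are \code{[0, e1]}, \code{(e1, e2]},
#' ..., \code{(em, Inf)}: a value landing exactly on an edge goes to the
#' lower (more significant) bin.
#'
#' @param evalues Numeric vector of E-values (>= 0).
#' @param binEdges Numeric vector of edges (default
#'   \code{c(1e-100, 1e-50, 1e-20, 1e-10, 1e-5, 1e-2, 1)}).
#' @param label Optional label for the distribution.
#' @return list of class \code{BinnedEvalueDistribution} with
#'   \code{bin_edges}, \code{counts} (length \code{length(binEdges) + 1}),
#'   \code{label}.
#' @export
binEvalues <- function(evalues,
                       binEdges = c(1e-100, 1e-50, 1e-20, 1e-10, 1e-5,
                                    1e-2, 1),
                       label = "") {
  stopifnot(all(evalues >= 0), !is.unsorted(binEdges, strictly = TRUE))
  bin <- vapply(evalues, function(v) 1L + sum(binEdges < v), integer(1))
  counts <- tabulate(bin, nbins = length(binEdges) + 1L)
  structure(list(label = label, bin_edges = binEdges, counts = counts),
            class = "BinnedEvalueDistribution")
}

#' Compare two binned E-value distributions
#'
#' Chi-square test of homogeneity on the 2 x B contingency table of bin
#' counts (no continuity correction). Bins empty in both distributions are
#' collapsed away; the degrees of freedom are B' - 1 over the remaining bins.
#'
#' @param distA,distB \code{BinnedEvalueDistribution}s on the same edges, or
#'   plain count vectors of equal length.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
compareEvalueDistributions <- function(distA, distB) {
  getCounts <- function(d) if (inherits(d, "BinnedEvalueDistribution")) d$counts else as.numeric(d)
  a <- getCounts(distA)
  b <- getCounts(distB)
  if (inherits(distA, "BinnedEvalueDistribution") &&
      inherits(distB, "BinnedEvalueDistribution") &&
      !isTRUE(all.equal(distA$bin_edges, distB$bin_edges)))
    stop("distributions use different bin edges", call. = FALSE)
  if (length(a) != length(b))
    stop("distributions have different numbers of bins", call. = FALSE)
  nonzero <- (a + b) > 0
  a <- a[nonzero]
  b <- b[nonzero]
  if (length(a) < 2)
    stop("chi-square undefined: fewer than 2 nonempty bins", call. = FALSE)
  if (sum(a) == 0 || sum(b) == 0)
    stop("chi-square undefined: one distribution is empty", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(rbind(a, b), correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Three-set Venn region counts for conserved domains
#'
#' Exclusive region counts for three identifier sets (e.g. unique conserved
#' domains found in two venoms and a reference venom database). The seven
#' regions sum to the size of the union.
#'
#' @param setA,setB,setC Character vectors of identifiers (duplicates
#'   ignored).
#' @return Named integer vector: \code{A_only}, \code{B_only}, \code{C_only},
#'   \code{AB_only}, \code{AC_only}, \code{BC_only}, \code{ABC}.
#' @export
domainOverlap <- function(setA, setB, setC) {
  a <- unique(setA); b <- unique(setB); c_ <- unique(setC)
  all_ids <- unique(c(a, b, c_))
  inA <- all_ids %in% a
  inB <- all_ids %in% b
  inC <- all_ids %in% c_
  c(A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB_only = sum(inA & inB & !inC),
    AC_only = sum(inA & !inB & inC),
    BC_only = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
}

#' Read BLAST 12-column tabular output
#'
#' The standard tabular dialect (outfmt 6): query, subject, identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore. Comment lines starting with \code{#} are skipped.
#'
#' @param file Path to the tabular file.
#' @return data.frame with those 12 columns.
#' @export
readBlastTab <- function(file) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(file, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, col.names = cols)
  df
}

#' Best hit per query
#'
#' Reduces a BLAST tabular result to one row per query, keeping the lowest
#' E-value (ties broken by highest bitscore, then input order) - the
#' single-best-hit semantics of running a search with max target seqs 1.
#'
#' @param hits data.frame from \code{\link{readBlastTab}}.
#' @return data.frame with one row per distinct query.
#' @export
bestHitPerQuery <- function(hits) {
  o <- order(hits$qseqid, hits$evalue, -hits$bitscore)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  rownames(h) <- NULL
  h
}
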