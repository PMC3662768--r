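# Peptide filter cascade, peptide-to-transcript mapping, and venom protein
# inference with spectral counting.

#' Peptide/protein filter settings
#'
#' The filter cascade applied to identified peptides and inferred proteins.
#' All probability/length thresholds are strict inequalities; the defaults
#' are the standard shotgun-proteomics quality cutoffs: peptide length > 4
#' residues, peptide probability > 0.5, +1 charge excluded, at least 2
#' distinct peptides per protein, protein probability > 0.7.
#'
#' @param minPeptideLen Exclusive peptide length cutoff (kept iff
#'   \code{nchar > minPeptideLen}).
#' @param minPeptideProb Exclusive peptide probability cutoff.
#' @param excludedCharges Integer charges removed outright (default +1:
#'   singly charged spectra fragment poorly and are unreliable).
#' @param minPeptidesPerProtein Minimum distinct peptides (after I/L
#'   collapsing) for a protein identification (kept iff \code{>=}).
#' @param minProteinProb Exclusive protein probability cutoff.
#' @param collapseIl Treat I and L as identical during matching and peptide
#'   counting (they are mass-indistinguishable isomers).
#' @return A list of class \code{FilterConfig}.
#' @export
filterConfig <- function(minPeptideLen = 4L, minPeptideProb = 0.5,
                         excludedCharges = 1L, minPeptidesPerProtein = 2L,
                         minProteinProb = 0.7, collapseIl = TRUE) {
  stopifnot(minPeptideLen >= 0, minPeptideProb >= 0, minPeptideProb <= 1,
            minPeptidesPerProtein >= 1, minProteinProb >= 0,
            minProteinProb <= 1)
  structure(list(minPeptideLen = as.integer(minPeptideLen),
                 minPeptideProb = minPeptideProb,
                 excludedCharges = as.integer(excludedCharges),
                 minPeptidesPerProtein = as.integer(minPeptidesPerProtein),
                 minProteinProb = minProteinProb,
                 collapseIl = isTRUE(collapseIl)),
            class = "FilterConfig")
}

#' Read an identified-peptide table
#'
#' Tab-separated columns \code{sequence}, \code{probability}, \code{charge},
#' \code{spectral_count}.
#'
#' @param file Path to the TSV.
#' @return data.frame of peptide observations.
#' @export
readPeptides <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sequence", "probability", "charge", "spectral_count")
  if (!all(need %in% names(df)))
    stop("peptide table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$sequence <- toupper(df$sequence)
  df
}

#' Write an identified-peptide table
#'
#' @param peptides data.frame of peptide observations.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writePeptides <- function(peptides, file) {
  utils::write.table(peptides, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Peptide filter cascade
#'
#' Keeps an observation iff its length exceeds \code{minPeptideLen}, its
#' probability exceeds \code{minPeptideProb} (both strict) and its charge is
#' not excluded. Idempotent.
#'
#' @param peptides data.frame with \code{sequence}, \code{probability},
#'   \code{charge} (and typically \code{spectral_count}).
#' @param config A \code{\link{filterConfig}}.
#' @return The kept rows, with attribute \code{"removed"} holding the rest.
#' @export
filterPeptides <- function(peptides, config = filterConfig()) {
  keep <- nchar(peptides$sequence) > config$minPeptideLen &
    peptides$probability > config$minPeptideProb &
    !(peptides$charge %in% config$excludedCharges)
  kept <- peptides[keep, , drop = FALSE]
  rownames(kept) <- NULL
  removed <- peptides[!keep, , drop = FALSE]
  rownames(removed) <- NULL
  attr(kept, "removed") <- removed
  kept
}

# Collapse filtered observations to distinct peptide keys (optionally under
# I/L equivalence): probability is the best observation, spectral counts sum.
.collapsePeptides <- function(peptides, collapseIl = TRUE) {
  key <- if (collapseIl) ilCollapse(peptides$sequence) else peptides$sequence
  o <- order(key)
  key <- key[o]
  agg <- data.frame(
    key = unique(key),
    stringsAsFactors = FALSE)
  agg$probability <- as.numeric(tapply(peptides$probability[o], key, max))
  spc <- peptides$spectral_count
  if (is.null(spc)) spc <- rep(1L, nrow(peptides))
  agg$spectral_count <- as.numeric(tapply(spc[o], key, sum))
  agg
}

#' Map peptides into the search database
#'
#' Exact substring matching of every kept peptide against every ORF segment,
#' with I and L treated as identical by default. All placements are reported;
#' a peptide's \code{unique_flag} is TRUE when it matches exactly one
#' transcript (multiple placements within one transcript still count as one
#' transcript hit).
#'
#' @param peptides data.frame of (filtered) peptide observations.
#' @param db A \code{\linkS4class{SearchDatabase}}.
#' @param collapseIl Match under I/L equivalence (default TRUE).
#' @return list with \code{matches} (data.frame: \code{peptide} = I/L
#'   collapsed key, \code{transcript_id}, \code{frame}, \code{segment} index
#'   into the database, \code{aa_start}/\code{aa_end} 0-based half-open
#'   within the ORF segment, \code{unique_flag}) and \code{unmatched}
#'   (character vector of peptide keys with no placement).
#' @export
mapPeptides <- function(peptides, db, collapseIl = TRUE) {
  pep <- .collapsePeptides(peptides, collapseIl = collapseIl)
  seg <- db@segments
  orf_chr <- as.character(db@orfs)
  if (collapseIl) orf_chr <- ilCollapse(orf_chr)
  # one concatenated subject with '*' separators: peptides never contain a
  # stop symbol, so no match can span a segment boundary
  subject <- Biostrings::AAString(paste(orf_chr, collapse = "*"))
  seg_start <- cumsum(c(0L, nchar(orf_chr) + 1L))[seq_along(orf_chr)]
  rows <- vector("list", nrow(pep))
  for (i in seq_len(nrow(pep))) {
    m <- Biostrings::matchPattern(pep$key[i], subject, fixed = TRUE)
    if (length(m) == 0) next
    st <- Biostrings::start(m) - 1L           # 0-based in concatenation
    si <- findInterval(st, seg_start)         # segment index
    rows[[i]] <- data.frame(peptide = pep$key[i],
                            segment = si,
                            aa_start = st - seg_start[si],
                            stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  unmatched <- pep$key[vapply(rows, is.null, logical(1))]
  if (is.null(matches)) {
    matches <- data.frame(peptide = character(), transcript_id = character(),
                          frame = character(), segment = integer(),
                          aa_start = integer(), aa_end = integer(),
                          unique_flag = logical(), stringsAsFactors = FALSE)
    return(list(matches = matches, unmatched = unmatched))
  }
  matches$transcript_id <- seg$transcript_id[matches$segment]
  matches$frame <- seg$frame[matches$segment]
  matches$aa_end <- matches$aa_start + nchar(matches$peptide)
  ntx <- vapply(split(matches$transcript_id, matches$peptide),
                function(v) length(unique(v)), integer(1))
  matches$unique_flag <- ntx[matches$peptide] == 1L
  matches <- matches[, c("peptide", "transcript_id", "frame", "segment",
                         "aa_start", "aa_end", "unique_flag")]
  rownames(matches) <- NULL
  list(matches = matches, unmatched = unmatched)
}

#' Coverage of an ORF by matched peptides
#'
#' Fraction of ORF residues covered by the union of matched peptide intervals
#' (overlaps merged). Order-invariant and monotone under adding matches.
#'
#' @param aaStart,aaEnd Integer vectors of 0-based half-open peptide
#'   intervals on the ORF.
#' @param orfLength ORF length in residues.
#' @return Proportion in [0, 1].
#' @examples
#' peptideCoverage(c(10, 15), c(20, 30), 100)  # 0.20
#' @export
peptideCoverage <- function(aaStart, aaEnd, orfLength) {
  stopifnot(orfLength > 0, length(aaStart) == length(aaEnd))
  if (length(aaStart) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = aaStart + 1L, end = aaEnd))
  sum(IRanges::width(ir)) / orfLength
}

#' Aggregated protein probability
#'
#' Independent-evidence aggregation over a protein's distinct retained
#' peptides: \code{1 - prod(1 - p_i)}. Monotonically non-decreasing as
#' peptides are added.
#'
#' @param probs Numeric vector of peptide probabilities in [0, 1].
#' @return Protein probability in [0, 1].
#' @export
proteinProbability <- function(probs) {
  stopifnot(all(probs >= 0 & probs <= 1))
  1 - prod(1 - probs)
}

#' Infer venom proteins from peptide matches
#'
#' Shared (non-unique) peptides are razor-assigned: each is credited to the
#' single candidate transcript with the highest current distinct-peptide
#' count (ties: higher assigned spectral count, then lexicographically
#' smallest id), processed in deterministic key order after unique peptides
#' have been credited. A transcript is identified iff it retains at least
#' \code{minPeptidesPerProtein} distinct peptides and its aggregated protein
#' probability exceeds \code{minProteinProb}. Every retained peptide counts
#' toward exactly one transcript.
#'
#' The representative ORF of an identification is the matched segment holding
#' the most assigned peptides (ties: longest, then first); coverage is the
#' merged-interval fraction of that segment, and normalized spectral
#' abundance is the length-normalized spectral count
#' \code{(SpC/L) / sum(SpC/L)} over all identifications (NSAF).
#'
#' @param mapping Result of \code{\link{mapPeptides}}.
#' @param peptides The filtered peptide observations (for probabilities and
#'   spectral counts).
#' @param db The \code{\linkS4class{SearchDatabase}} used for mapping.
#' @param config A \code{\link{filterConfig}}.
#' @return data.frame with one row per identified protein:
#'   \code{transcript_id}, \code{frame}, \code{orf_start}, \code{orf_length},
#'   \code{distinct_peptides}, \code{total_spectral_count},
#'   \code{protein_probability}, \code{coverage}, \code{nsaf}; attribute
#'   \code{"assignments"} maps each retained peptide key to its transcript.
#' @export
inferProteins <- function(mapping, peptides, db, config = filterConfig()) {
  matches <- mapping$matches
  empty <- data.frame(transcript_id = character(), frame = character(),
                      orf_start = integer(), orf_length = integer(),
                      distinct_peptides = integer(),
                      total_spectral_count = numeric(),
                      protein_probability = numeric(), coverage = numeric(),
                      nsaf = numeric(), stringsAsFactors = FALSE)
  if (nrow(matches) == 0) return(empty)
  pep <- .collapsePeptides(peptides, collapseIl = config$collapseIl)
  pep <- pep[pep$key %in% matches$peptide, , drop = FALSE]
  prob <- stats::setNames(pep$probability, pep$key)
  spc <- stats::setNames(pep$spectral_count, pep$key)

  tx_by_pep <- lapply(split(matches$transcript_id, matches$peptide), unique)
  is_unique <- lengths(tx_by_pep) == 1L
  txs <- sort(unique(matches$transcript_id))
  n_pep <- stats::setNames(integer(length(txs)), txs)
  spc_tx <- stats::setNames(numeric(length(txs)), txs)
  assign_to <- character(0)

  for (k in names(tx_by_pep)[is_unique]) {
    t <- tx_by_pep[[k]]
    assign_to[k] <- t
    n_pep[t] <- n_pep[t] + 1L
    spc_tx[t] <- spc_tx[t] + spc[k]
  }
  for (k in sort(names(tx_by_pep)[!is_unique])) {
    cand <- tx_by_pep[[k]]
    o <- order(-n_pep[cand], -spc_tx[cand], cand)
    t <- cand[o[1L]]
    assign_to[k] <- t
    n_pep[t] <- n_pep[t] + 1L
    spc_tx[t] <- spc_tx[t] + spc[k]
  }

  keep_tx <- names(n_pep)[n_pep >= config$minPeptidesPerProtein]
  rows <- lapply(keep_tx, function(t) {
    keys <- names(assign_to)[assign_to == t]
    pp <- proteinProbability(prob[keys])
    if (!(pp > config$minProteinProb)) return(NULL)
    mt <- matches[matches$transcript_id == t & matches$peptide %in% keys, ,
                  drop = FALSE]
    # representative ORF: segment with most distinct assigned peptides;
    # ties by longest segment, then first
    per_seg <- vapply(split(mt$peptide, mt$segment),
                      function(v) length(unique(v)), integer(1))
    segs <- as.integer(names(per_seg))
    o <- order(-per_seg, -db@segments$width[segs], segs)
    rep_seg <- segs[o[1L]]
    inseg <- mt[mt$segment == rep_seg, , drop = FALSE]
    # one interval per distinct peptide placement
    inseg <- unique(inseg[, c("peptide", "aa_start", "aa_end")])
    L <- db@segments$width[rep_seg]
    data.frame(transcript_id = t,
               frame = db@segments$frame[rep_seg],
               orf_start = db@segments$aa_start[rep_seg],
               orf_length = L,
               distinct_peptides = length(keys),
               total_spectral_count = sum(spc[keys]),
               protein_probability = pp,
               coverage = peptideCoverage(inseg$aa_start, inseg$aa_end, L),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  ids <- do.call(rbind, rows)
  ids <- ids[order(-ids$distinct_peptides, ids$transcript_id), , drop = FALSE]
  saf <- ids$total_spectral_count / ids$orf_length
  ids$nsaf <- saf / sum(saf)
  rownames(ids) <- NULL
  attr(ids, "assignments") <- assign_to
  ids
}

#' Identification-level summary
#'
#' Global averages mirroring a proteomics results table: mean distinct
#' peptide hits per protein, mean coverage (percent), and peptide retention
#' through the filter cascade.
#'
#' @param identifications Result of \code{\link{inferProteins}}.
#' @param nInitialPeptides,nKeptPeptides Peptide counts before/after the
#'   filter cascade (optional; retention reported when given).
#' @return list with \code{n_proteins}, \code{mean_distinct_peptides},
#'   \code{mean_coverage_percent}, and (when counts are given)
#'   \code{n_initial}, \code{n_kept}, \code{retained_percent}.
#' @export
spectralSummary <- function(identifications, nInitialPeptides = NULL,
                            nKeptPeptides = NULL) {
  out <- list(n_proteins = nrow(identifications),
              mean_distinct_peptides =
                if (nrow(identifications)) mean(identifications$distinct_peptides) else NA_real_,
              mean_coverage_percent =
                if (nrow(identifications)) 100 * mean(identifications$coverage) else NA_real_)
  if (!is.null(nInitialPeptides) && !is.null(nKeptPeptides)) {
    out$n_initial <- nInitialPeptides
    out$n_kept <- nKeptPeptides
    out$retained_percent <- reportPercent(nKeptPeptides, nInitialPeptides)
  }
  out
}
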