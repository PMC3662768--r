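#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' TranscriptomeSet: contigs with read counts and TPM
#'
#' Container for a set of assembled transcripts (contigs) together with
#' per-transcript read counts and TPM expression estimates. Sequences are
#' stored as an upper-case \code{DNAStringSet}; counts and TPM start as
#' \code{NA} and are filled in by \code{\link{estimateTpm}}.
#'
#' @slot sequences \code{DNAStringSet} with unique, non-empty names.
#' @slot readCount numeric vector parallel to \code{sequences}; fractional
#'   values are allowed after EM resolution of ambiguous counts.
#' @slot tpm numeric vector parallel to \code{sequences}; over any quantified
#'   set with a positive count, TPM sums to 1e6 before filtering.
#'
#' @seealso \code{\link{readTranscripts}}, \code{\link{estimateTpm}},
#'   \code{\link{filterExpressed}}, \code{\link{assemblyStats}}
#' @export
setClass("TranscriptomeSet",
         slots = c(sequences = "DNAStringSet",
                   readCount = "numeric",
                   tpm = "numeric"))

setValidity("TranscriptomeSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  n <- length(object@sequences)
  if (n > 0 && (is.null(ids) || any(ids == "") || anyNA(ids)))
    msg <- c(msg, "all transcripts must be named")
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate transcript ids")
  if (n > 0 && any(Biostrings::width(object@sequences) == 0))
    msg <- c(msg, "empty sequences are not allowed")
  if (length(object@readCount) != n || length(object@tpm) != n)
    msg <- c(msg, "readCount and tpm must be parallel to sequences")
  if (any(object@readCount < 0, na.rm = TRUE))
    msg <- c(msg, "read counts must be non-negative")
  if (any(object@tpm < 0, na.rm = TRUE))
    msg <- c(msg, "tpm must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptomeSet
#'
#' @param sequences A named \code{DNAStringSet} (or named character vector of
#'   nucleotide sequences; lower case is normalized to upper case).
#' @param readCount,tpm Optional numeric vectors parallel to the sequences.
#' @return A \code{\linkS4class{TranscriptomeSet}}.
#' @export
TranscriptomeSet <- function(sequences,
                             readCount = rep(NA_real_, length(sequences)),
                             tpm = rep(NA_real_, length(sequences))) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  new("TranscriptomeSet", sequences = sequences,
      readCount = as.numeric(readCount), tpm = as.numeric(tpm))
}

#' SearchDatabase: six-frame translated ORF segments
#'
#' The peptide-search space: every stop-free run (ORF segment) of at least
#' \code{minAaLen} residues from the six-frame translation of a transcript
#' set. Coordinates are 0-based half-open within each frame translation.
#'
#' @slot orfs \code{AAStringSet} of stop-free segments, named
#'   \code{transcript_id|frame|aa_start}.
#' @slot segments data.frame with columns \code{transcript_id}, \code{frame}
#'   (one of \code{"+1".."+3","-1".."-3"}), \code{aa_start}, \code{aa_end},
#'   \code{width}.
#' @slot minAaLen integer minimum segment length retained.
#'
#' @seealso \code{\link{buildSearchDatabase}}, \code{\link{mapPeptides}}
#' @export
setClass("SearchDatabase",
         slots = c(orfs = "AAStringSet",
                   segments = "data.frame",
                   minAaLen = "integer"))

setValidity("SearchDatabase", function(object) {
  msg <- character()
  seg <- object@segments
  need <- c("transcript_id", "frame", "aa_start", "aa_end", "width")
  if (!all(need %in% names(seg)))
    msg <- c(msg, "segments must have transcript_id/frame/aa_start/aa_end/width")
  else {
    if (nrow(seg) != length(object@orfs))
      msg <- c(msg, "segments and orfs must be parallel")
    if (nrow(seg) > 0) {
      if (!all(seg$frame %in% c("+1", "+2", "+3", "-1", "-2", "-3")))
        msg <- c(msg, "invalid frame labels")
      if (!all(seg$aa_end - seg$aa_start == Biostrings::width(object@orfs)))
        msg <- c(msg, "segment coordinates inconsistent with sequences")
    }
  }
  if (length(msg)) msg else TRUE
})

#' VenomScenario: a ground-truthed synthetic data set
#'
#' Holds everything a pipeline run needs (transcripts with read counts,
#' identified-peptide table, GO annotation map, optional homology E-values)
#' together with the generating truth, so recovery can be scored.
#'
#' @slot transcripts \code{\linkS4class{TranscriptomeSet}} (read counts set).
#' @slot countTable data.frame \code{transcript_id,length_bp,count,ambiguity_group}.
#' @slot peptides data.frame \code{sequence,probability,charge,spectral_count}.
#' @slot goMap named list: gene id to character vector of GO term ids.
#' @slot evalues data.frame \code{transcript_id,subset,evalue} (may be empty).
#' @slot truth list with elements \code{label}, \code{abundance},
#'   \code{signal}, \code{peptide_origin}, \code{enriched_terms} (see
#'   \code{\link{simulateScenario}}).
#' @slot config the \code{\link{scenarioConfig}} used.
#' @export
setClass("VenomScenario",
         slots = c(transcripts = "TranscriptomeSet",
                   countTable = "data.frame",
                   peptides = "data.frame",
                   goMap = "list",
                   evalues = "data.frame",
                   truth = "list",
                   config = "list"))

setValidity("VenomScenario", function(object) {
  msg <- character()
  ids <- names(object@transcripts@sequences)
  tr <- object@truth
  if (!all(c("label", "abundance", "signal", "peptide_origin") %in% names(tr)))
    msg <- c(msg, "truth must carry label/abundance/signal/peptide_origin")
  else {
    if (!all(names(tr$label) %in% ids) || length(tr$label) != length(ids))
      msg <- c(msg, "truth labels must cover exactly the generated transcripts")
    orig <- tr$peptide_origin
    if (length(orig) && !all(orig %in% c(ids, "contaminant")))
      msg <- c(msg, "peptide origins must resolve to a transcript or 'contaminant'")
  }
  if (length(msg)) msg else TRUE
})

#' VenomReport: end-to-end pipeline results
#'
#' Structured result of \code{\link{runPipeline}}: assembly statistics before
#' and after expression filtering, the peptide filter audit, venom protein
#' identifications with spectral summaries, secretion-signal enrichment, GO
#' enrichment, recovery against planted truth (when available) and a
#' provenance block. Every printed percentage is accompanied by its
#' numerator/denominator pair and recomputed by \code{\link{reportPercent}}.
#'
#' @slot assembly data.frame mirroring the assembly-statistics table
#'   (initial and expression-filtered rows).
#' @slot peptides list: counts before/after the filter cascade and retention.
#' @slot identifications data.frame, one row per venom protein.
#' @slot summary list of identification-level averages.
#' @slot signal list: per-class signal fractions and the chi-square result.
#' @slot enrichment data.frame of GO enrichment results.
#' @slot recovery list (sensitivity/precision vs truth) or empty.
#' @slot provenance list: config echo, seed, package version.
#' @export
setClass("VenomReport",
         slots = c(assembly = "data.frame",
                   peptides = "list",
                   identifications = "data.frame",
                   summary = "list",
                   signal = "list",
                   enrichment = "data.frame",
                   recovery = "list",
                   provenance = "list"))

setValidity("VenomReport", function(object) {
  msg <- character()
  a <- object@assembly
  if (nrow(a) && !is.null(a$percent_of_initial)) {
    chk <- !is.na(a$percent_of_initial)
    ok <- a$percent_of_initial[chk] ==
      reportPercent(a$n_transcripts[chk], a$n_transcripts[1L])
    if (!all(ok)) msg <- c(msg, "assembly percentages inconsistent")
  }
  p <- object@peptides
  if (length(p) && !is.null(p$retained_percent) && p$n_initial > 0) {
    if (!identical(as.integer(p$retained_percent),
                   reportPercent(p$n_kept, p$n_initial)))
      msg <- c(msg, "peptide retention percentage inconsistent")
  }
  if (length(msg)) msg else TRUE
})
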