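# Transcriptome ingestion, assembly statistics, TPM quantification and the
# expression filter.

#' Read assembled transcripts from FASTA
#'
#' Ingests contigs into a \code{\linkS4class{TranscriptomeSet}}. Sequence ids
#' are the first whitespace-delimited token of each header; sequences are
#' normalized to upper case. Duplicate ids and empty sequences are format
#' errors.
#'
#' @param file Path to a FASTA file of nucleotide contigs.
#' @return A \code{\linkS4class{TranscriptomeSet}} (counts and TPM unset).
#' @export
readTranscripts <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(Biostrings::width(seqs) == 0))
    stop("empty sequence(s) in FASTA: ",
         paste(ids[Biostrings::width(seqs) == 0], collapse = ", "),
         call. = FALSE)
  names(seqs) <- ids
  TranscriptomeSet(seqs)
}

#' Write transcripts to FASTA
#'
#' @param x A \code{\linkS4class{TranscriptomeSet}}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeTranscripts <- function(x, file) {
  Biostrings::writeXStringSet(sequences(x), file)
  invisible(file)
}

#' N50 of a set of lengths
#'
#' The N50 is the length L such that transcripts of at least L bp together
#' contain at least half of the total assembled sequence: sort lengths in
#' descending order, accumulate, and report the length at which the running
#' sum first reaches half the total.
#'
#' @param lengths Numeric vector of transcript lengths in bp.
#' @return The N50 (0 for an empty set).
#' @examples
#' n50(c(700, 500, 300, 300, 200, 200, 200))  # 500
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0)
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(l)
  l[which(cs >= sum(l) / 2)[1L]]
}

#' Assembly statistics
#'
#' Mirrors the standard assembly report: number of transcripts longer than
#' \code{minReportLength} bp, N50 and mean length. N50 and mean length are
#' computed over all transcripts in the set.
#'
#' @param x A \code{\linkS4class{TranscriptomeSet}} or numeric length vector.
#' @param minReportLength Length cutoff (bp) for the transcript count column
#'   (strictly greater than; default 100).
#' @return A one-row data.frame with \code{n_transcripts}, \code{n50},
#'   \code{mean_length} (zeros for an empty set).
#' @export
assemblyStats <- function(x, minReportLength = 100) {
  lens <- if (methods::is(x, "TranscriptomeSet")) {
    as.numeric(Biostrings::width(sequences(x)))
  } else as.numeric(x)
  if (length(lens) == 0)
    return(data.frame(n_transcripts = 0L, n50 = 0, mean_length = 0))
  data.frame(n_transcripts = sum(lens > minReportLength),
             n50 = n50(lens),
             mean_length = mean(lens))
}

#' Quantification settings
#'
#' @param tpmThreshold Expression filter threshold in TPM (default 1; the
#'   recommended cutoff for separating expressed transcripts from assembly
#'   artifacts). Kept transcripts satisfy \code{tpm >= tpmThreshold}.
#' @param minReportLength Length cutoff (bp) for assembly report counts.
#' @param emMaxIter,emTolerance EM stopping rule for ambiguous counts:
#'   iterate until every abundance changes by less than \code{emTolerance}
#'   (relative) or \code{emMaxIter} rounds.
#' @return A list of class \code{QuantConfig}.
#' @export
quantConfig <- function(tpmThreshold = 1, minReportLength = 100,
                        emMaxIter = 200L, emTolerance = 1e-8) {
  stopifnot(tpmThreshold >= 0, emTolerance > 0, emMaxIter >= 1)
  structure(list(tpmThreshold = tpmThreshold,
                 minReportLength = minReportLength,
                 emMaxIter = as.integer(emMaxIter),
                 emTolerance = emTolerance),
            class = "QuantConfig")
}

#' Read a count table
#'
#' Tab-separated columns \code{transcript_id}, \code{length_bp},
#' \code{count}, and optional \code{ambiguity_group} (empty for uniquely
#' mapped counts).
#'
#' @param file Path to the TSV.
#' @return data.frame with those columns (\code{ambiguity_group} as
#'   character, \code{NA} where empty).
#' @export
readCountTable <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "length_bp", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns transcript_id, length_bp, count",
         call. = FALSE)
  if (is.null(df$ambiguity_group)) df$ambiguity_group <- NA_character_
  df$ambiguity_group <- as.character(df$ambiguity_group)
  df$ambiguity_group[df$ambiguity_group == ""] <- NA_character_
  df
}

#' Write a count table
#'
#' @param counts data.frame as produced by \code{\link{readCountTable}}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeCountTable <- function(counts, file) {
  counts$ambiguity_group[is.na(counts$ambiguity_group)] <- ""
  utils::write.table(counts, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# EM resolution of ambiguous counts. u: unique counts per transcript; groups:
# list of (members = integer indices, count); len: transcript lengths.
# Each ambiguous count is split across its group's transcripts proportionally
# to the current length-normalized abundance (read rate) estimates.
.emResolve <- function(u, groups, len, maxIter, tol) {
  a <- u
  for (g in groups) a[g$members] <- a[g$members] + g$count / length(g$members)
  if (length(groups) == 0) return(a)
  for (it in seq_len(maxIter)) {
    rho <- a / len
    a_new <- u
    for (g in groups) {
      w <- rho[g$members]
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
      a_new[g$members] <- a_new[g$members] + g$count * w
    }
    delta <- max(abs(a_new - a) / pmax(a, 1))
    a <- a_new
    if (delta < tol) break
  }
  a
}

#' Estimate TPM expression
#'
#' Length-normalized expression in transcripts per million:
#' \code{tpm_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6}. Uniquely mapped
#' counts contribute wholly to their transcript; counts carrying an
#' ambiguity-group id are split across the group's transcripts proportionally
#' to the current abundance estimates and iterated to convergence (EM). With
#' no ambiguity groups the result equals the closed-form rate formula.
#'
#' @param x A \code{\linkS4class{TranscriptomeSet}}.
#' @param counts data.frame with \code{transcript_id}, \code{count} and
#'   optional \code{ambiguity_group} (see \code{\link{readCountTable}}), or a
#'   named numeric vector of unique counts.
#' @param config A \code{\link{quantConfig}}.
#' @return \code{x} with \code{readCount} (post-EM, fractional) and
#'   \code{tpm} filled in. All-zero counts give all-zero TPM.
#' @export
estimateTpm <- function(x, counts, config = quantConfig()) {
  ids <- transcriptIds(x)
  len <- as.numeric(Biostrings::width(sequences(x)))
  if (is.numeric(counts) && !is.data.frame(counts)) {
    counts <- data.frame(transcript_id = names(counts),
                         count = as.numeric(counts),
                         ambiguity_group = NA_character_,
                         stringsAsFactors = FALSE)
  }
  idx <- match(counts$transcript_id, ids)
  if (anyNA(idx))
    stop("count table references unknown transcript(s): ",
         paste(unique(counts$transcript_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  if (any(counts$count < 0)) stop("negative counts", call. = FALSE)
  grp <- counts$ambiguity_group
  if (is.null(grp)) grp <- rep(NA_character_, nrow(counts))
  uniq <- is.na(grp)
  u <- numeric(length(ids))
  if (any(uniq)) {
    agg <- tapply(counts$count[uniq], idx[uniq], sum)
    u[as.integer(names(agg))] <- as.numeric(agg)
  }
  groups <- list()
  if (any(!uniq)) {
    for (g in split(which(!uniq), grp[!uniq])) {
      cnt <- unique(counts$count[g])
      if (length(cnt) != 1L)
        stop("ambiguity group with inconsistent counts: ",
             grp[g[1L]], call. = FALSE)
      groups[[length(groups) + 1L]] <- list(members = unique(idx[g]),
                                            count = cnt)
    }
  }
  a <- .emResolve(u, groups, len, config$emMaxIter, config$emTolerance)
  rate <- a / len
  x@readCount <- a
  x@tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rep(0, length(ids))
  methods::validObject(x)
  x
}

#' Expression filter
#'
#' Partitions a quantified transcript set at a TPM threshold: transcripts at
#' or above the threshold are kept as expressed, the rest (assembly
#' artifacts, incomplete contigs) removed. The boundary is inclusive, so the
#' stated threshold value itself is retained.
#'
#' @param x A quantified \code{\linkS4class{TranscriptomeSet}}.
#' @param tpmThreshold TPM cutoff (default 1).
#' @return list with \code{kept} and \code{removed}
#'   \code{TranscriptomeSet}s, counts \code{n_kept}/\code{n_total}, and
#'   \code{retained_percent} (integer, rounded half away from zero).
#' @export
filterExpressed <- function(x, tpmThreshold = 1) {
  if (all(is.na(x@tpm)) && length(x) > 0)
    stop("tpm not computed; run estimateTpm() first", call. = FALSE)
  keep <- !is.na(x@tpm) & x@tpm >= tpmThreshold
  list(kept = x[which(keep)],
       removed = x[which(!keep)],
       n_kept = sum(keep),
       n_total = length(x),
       retained_percent = reportPercent(sum(keep), length(x)))
}
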