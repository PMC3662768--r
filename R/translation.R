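# Six-frame translation and ORF extraction: construction of the
# peptide-search database.

FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

# Translate a DNAStringSet at a fixed offset (0/1/2) on the given strand,
# standard genetic code; codons containing N become 'X', stops become '*'.
.translateOffset <- function(seqs, offset) {
  w <- Biostrings::width(seqs)
  usable <- 3L * ((w - offset) %/% 3L)
  usable[usable < 0L] <- 0L
  sub <- Biostrings::subseq(seqs, start = offset + 1L, width = usable)
  # plain codon-table semantics: no alternative-initiator handling
  Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE)
}

#' Six-frame translation
#'
#' Translates each transcript in all three reading frames on both strands,
#' yielding six amino-acid sequences per transcript. Frames \code{+1..+3}
#' start at offsets 0..2 of the forward strand; \code{-1..-3} at offsets 0..2
#' of the reverse complement. The standard genetic code is used; stop codons
#' are rendered \code{*} and codons containing \code{N} translate to
#' \code{X}. Sequences shorter than a codon give empty translations.
#'
#' @param x A \code{\linkS4class{TranscriptomeSet}}, \code{DNAStringSet}, or
#'   character vector of nucleotide sequences (named).
#' @return data.frame with one row per (transcript, frame):
#'   \code{transcript_id}, \code{frame}, \code{nt_offset} (0-based offset on
#'   the frame's strand), \code{aa} (translation, character).
#' @export
sixFrameTranslate <- function(x) {
  seqs <- if (methods::is(x, "TranscriptomeSet")) sequences(x)
  else if (methods::is(x, "DNAStringSet")) x
  else Biostrings::DNAStringSet(toupper(x))
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (length(seqs) == 0)
    return(data.frame(transcript_id = character(), frame = character(),
                      nt_offset = integer(), aa = character(),
                      stringsAsFactors = FALSE))
  rc <- Biostrings::reverseComplement(seqs)
  out <- vector("list", 6L)
  for (k in 0:2) {
    out[[k + 1L]] <- data.frame(
      transcript_id = names(seqs), frame = FRAMES[k + 1L], nt_offset = k,
      aa = as.character(.translateOffset(seqs, k)),
      stringsAsFactors = FALSE)
    out[[k + 4L]] <- data.frame(
      transcript_id = names(seqs), frame = FRAMES[k + 4L], nt_offset = k,
      aa = as.character(.translateOffset(rc, k)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$transcript_id, names(seqs)),
                   match(res$frame, FRAMES)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract ORF segments from frame translations
#'
#' Splits each translation into maximal stop-free runs (the stop-to-stop ORF
#' convention: no start codon is required, because peptides can map anywhere
#' in a coding region). Coordinates are 0-based half-open within the frame
#' translation.
#'
#' @param aa Character vector of amino-acid translations (may contain
#'   \code{*}).
#' @param minAaLen Minimum segment length retained (>= 1).
#' @return data.frame with \code{input_index}, \code{aa_start},
#'   \code{aa_end}, \code{sequence}; segments within a translation are
#'   non-overlapping and ordered.
#' @examples
#' extractOrfs("MK*GGGG*A", minAaLen = 2)  # "MK" and "GGGG"
#' @export
extractOrfs <- function(aa, minAaLen = 5L) {
  stopifnot(minAaLen >= 1)
  parts <- strsplit(aa, "*", fixed = TRUE)
  n_per <- lengths(parts)
  seg <- unlist(parts, use.names = FALSE)
  if (length(seg) == 0)
    return(data.frame(input_index = integer(), aa_start = integer(),
                      aa_end = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  idx <- rep(seq_along(aa), n_per)
  w <- nchar(seg)
  # segment k starts after the cumulative length of earlier segments plus one
  # stop separator each, reset per input string
  starts <- unlist(lapply(parts, function(p) {
    if (length(p) == 0) return(integer())
    cumsum(c(0L, nchar(p)[-length(p)] + 1L))
  }), use.names = FALSE)
  keep <- w >= minAaLen
  data.frame(input_index = idx[keep],
             aa_start = starts[keep],
             aa_end = starts[keep] + w[keep],
             sequence = seg[keep],
             stringsAsFactors = FALSE)
}

#' Build the translated peptide-search database
#'
#' Six-frame translates every transcript and extracts stop-free ORF segments
#' of at least \code{minAaLen} residues (default 5: the shortest peptide
#' passing the >4-residue filter must fit). Segment names encode their origin
#' as \code{transcript_id|frame|aa_start}.
#'
#' @param x A \code{\linkS4class{TranscriptomeSet}} (typically the
#'   expression-filtered set) or \code{DNAStringSet}.
#' @param minAaLen Minimum ORF length in residues.
#' @return A \code{\linkS4class{SearchDatabase}}.
#' @export
buildSearchDatabase <- function(x, minAaLen = 5L) {
  tr <- sixFrameTranslate(x)
  orfs <- extractOrfs(tr$aa, minAaLen = minAaLen)
  seg <- data.frame(transcript_id = tr$transcript_id[orfs$input_index],
                    frame = tr$frame[orfs$input_index],
                    aa_start = orfs$aa_start,
                    aa_end = orfs$aa_end,
                    width = orfs$aa_end - orfs$aa_start,
                    stringsAsFactors = FALSE)
  aas <- Biostrings::AAStringSet(orfs$sequence)
  names(aas) <- sprintf("%s|%s|%d", seg$transcript_id, seg$frame,
                        seg$aa_start)
  new("SearchDatabase", orfs = aas, segments = seg,
      minAaLen = as.integer(minAaLen))
}

#' Write the search database as FASTA
#'
#' Headers are \code{transcript_id|frame|aa_start} so external search engines
#' can consume the database and hits remain traceable to transcript
#' coordinates.
#'
#' @param db A \code{\linkS4class{SearchDatabase}}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeSearchDatabase <- function(db, file) {
  Biostrings::writeXStringSet(db@orfs, file)
  invisible(file)
}

#' Longest ORF of a transcript
#'
#' The single longest stop-free segment across all six frames, used as the
#' representative protein product for annotation and secretion-signal
#' analysis. Ties are broken by frame order (+1, +2, +3, -1, -2, -3), then by
#' smallest start coordinate.
#'
#' @param x A nucleotide sequence (character or \code{DNAString}), or a
#'   \code{\linkS4class{TranscriptomeSet}} (then one row per transcript is
#'   returned).
#' @return A one-row data.frame (\code{transcript_id}, \code{frame},
#'   \code{aa_start}, \code{aa_end}, \code{sequence}) or, for a set, one row
#'   per transcript with at least one ORF. Transcripts without any stop-free
#'   residue are absent from the result (and a zero-row frame is returned for
#'   a single such input).
#' @export
longestOrf <- function(x) {
  if (!methods::is(x, "TranscriptomeSet")) {
    x <- TranscriptomeSet(Biostrings::DNAStringSet(
      stats::setNames(toupper(as.character(x)), "query")))
    single <- TRUE
  } else single <- FALSE
  db <- buildSearchDatabase(x, minAaLen = 1L)
  seg <- db@segments
  seg$sequence <- as.character(db@orfs)
  if (nrow(seg) == 0) return(seg)
  ord <- order(match(seg$transcript_id, transcriptIds(x)),
               -seg$width, match(seg$frame, FRAMES), seg$aa_start)
  seg <- seg[ord, , drop = FALSE]
  res <- seg[!duplicated(seg$transcript_id), , drop = FALSE]
  rownames(res) <- NULL
  if (single) res$transcript_id <- NULL
  res
}
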