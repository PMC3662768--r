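#' @include AllClasses.R
NULL

#' Accessors for TranscriptomeSet
#'
#' @param x A \code{\linkS4class{TranscriptomeSet}}.
#' @return \code{transcriptIds}: character vector of ids;
#'   \code{transcriptLengths}: integer widths in bp; \code{readCounts} and
#'   \code{tpm}: named numeric vectors; \code{sequences}: the
#'   \code{DNAStringSet}.
#' @name TranscriptomeSet-accessors
NULL

#' @rdname TranscriptomeSet-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptomeSet-accessors
#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))

#' @rdname TranscriptomeSet-accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname TranscriptomeSet-accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname TranscriptomeSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname TranscriptomeSet-accessors
setMethod("transcriptIds", "TranscriptomeSet",
          function(x) names(x@sequences))

#' @rdname TranscriptomeSet-accessors
setMethod("transcriptLengths", "TranscriptomeSet",
          function(x) stats::setNames(Biostrings::width(x@sequences),
                                      names(x@sequences)))

#' @rdname TranscriptomeSet-accessors
setMethod("readCounts", "TranscriptomeSet",
          function(x) stats::setNames(x@readCount, names(x@sequences)))

#' @rdname TranscriptomeSet-accessors
setMethod("tpm", "TranscriptomeSet",
          function(x) stats::setNames(x@tpm, names(x@sequences)))

#' @rdname TranscriptomeSet-accessors
setMethod("sequences", "TranscriptomeSet", function(x) x@sequences)

setMethod("length", "TranscriptomeSet", function(x) length(x@sequences))

setMethod("[", "TranscriptomeSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("TranscriptomeSet", sequences = x@sequences[i],
      readCount = x@readCount[i], tpm = x@tpm[i])
})

setMethod("show", "TranscriptomeSet", function(object) {
  n <- length(object)
  cat(sprintf("TranscriptomeSet with %d transcript%s\n", n,
              if (n == 1) "" else "s"))
  if (n > 0) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  length: %d-%d bp (mean %.1f)\n", min(w), max(w), mean(w)))
    cat(sprintf("  read counts: %s; TPM: %s\n",
                if (all(is.na(object@readCount))) "unset" else "set",
                if (all(is.na(object@tpm))) "unset" else "set"))
  }
})

setMethod("show", "SearchDatabase", function(object) {
  cat(sprintf("SearchDatabase: %d ORF segments (>= %d aa) from %d transcripts\n",
              nrow(object@segments), object@minAaLen,
              length(unique(object@segments$transcript_id))))
})

setMethod("show", "VenomScenario", function(object) {
  lab <- table(factor(object@truth$label,
                      levels = c("venom", "body", "artifact")))
  cat("VenomScenario\n")
  cat(sprintf("  transcripts: %d (venom %d, body %d, artifact %d)\n",
              length(object@transcripts), lab[["venom"]], lab[["body"]],
              lab[["artifact"]]))
  cat(sprintf("  peptide rows: %d (%d contaminant)\n", nrow(object@peptides),
              sum(object@truth$peptide_origin == "contaminant")))
  cat(sprintf("  GO terms: %d (%d planted enriched); seed %s\n",
              length(unique(unlist(object@goMap))),
              length(object@truth$enriched_terms),
              object@config$seed))
})

setMethod("show", "VenomReport", function(object) {
  cat("VenomReport\n== Assembly ==\n")
  print(object@assembly, row.names = FALSE)
  p <- object@peptides
  cat(sprintf("== Peptides ==\n  %d observed, %d passed filters (%s%%)\n",
              p$n_initial, p$n_kept, p$retained_percent))
  cat(sprintf("== Identifications ==\n  %d venom proteins; mean peptide hits %.1f; mean coverage %.1f%%\n",
              nrow(object@identifications),
              object@summary$mean_distinct_peptides,
              object@summary$mean_coverage_percent))
  s <- object@signal
  if (length(s)) {
    cat(sprintf("== Secretion signals ==\n  venom %d/%d (%d%%) vs body %d/%d (%d%%); chi-square %.2f, p = %.3g\n",
                s$venom_k, s$venom_n, s$venom_percent,
                s$body_k, s$body_n, s$body_percent,
                s$chisq$statistic, s$chisq$p_value))
  }
  if (nrow(object@enrichment)) {
    sig <- sum(object@enrichment$significant)
    cat(sprintf("== GO enrichment ==\n  %d/%d terms significant after Bonferroni\n",
                sig, nrow(object@enrichment)))
  }
  if (length(object@recovery)) {
    cat(sprintf("== Recovery vs planted truth ==\n  sensitivity %.3f, precision %.3f\n",
                object@recovery$sensitivity, object@recovery$precision))
  }
})
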