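# End-to-end orchestration: quantify -> filter -> translate -> map -> infer
# -> validate -> enrich, with a structured report.

#' Pipeline configuration
#'
#' Thresholds for every stage, defaulting to the published filter cascade:
#' 1 TPM expression filter, ORFs of at least 5 residues, peptide length > 4,
#' peptide probability > 0.5, +1 charge excluded, >= 2 peptides per protein,
#' protein probability > 0.7, Bonferroni alpha 0.05.
#'
#' @param quant A \code{\link{quantConfig}}.
#' @param filter A \code{\link{filterConfig}}.
#' @param minOrfLen Minimum ORF length (residues) in the search database.
#' @param alpha Bonferroni significance level for GO enrichment.
#' @param bodyConvention For the signal chi-square: compare venom proteins
#'   against \code{"all_minus_venom"} (default) or \code{"all"} expressed
#'   transcripts.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(quant = quantConfig(), filter = filterConfig(),
                           minOrfLen = 5L, alpha = 0.05,
                           bodyConvention = c("all_minus_venom", "all")) {
  structure(list(quant = quant, filter = filter,
                 minOrfLen = as.integer(minOrfLen), alpha = alpha,
                 bodyConvention = match.arg(bodyConvention)),
            class = "PipelineConfig")
}

#' Extrapolate the number of true venom genes
#'
#' Scales an identification count by an independently validated true-positive
#' rate (e.g. the fraction of randomly selected identifications confirmed by
#' venom-gland RT-PCR), truncating to an integer.
#'
#' @param identifiedCount Number of identified proteins.
#' @param validatedPositive,validatedTotal Confirmed and attempted
#'   validations.
#' @return \code{floor(identifiedCount * validatedPositive / validatedTotal)}.
#' @examples
#' extrapolateTruePositives(129, 19, 20)  # 122
#' extrapolateTruePositives(176, 19, 20)  # 167
#' @export
extrapolateTruePositives <- function(identifiedCount, validatedPositive,
                                     validatedTotal) {
  stopifnot(validatedTotal > 0, validatedPositive >= 0,
            validatedPositive <= validatedTotal, identifiedCount >= 0)
  floor(identifiedCount * validatedPositive / validatedTotal)
}

#' Run the full identification pipeline
#'
#' Executes every stage in order on a synthetic scenario or on files:
#' expression quantification (TPM with EM), the 1-TPM expression filter,
#' six-frame translation into the ORF search database, the peptide filter
#' cascade, exact peptide-to-ORF mapping with I/L equivalence, razor protein
#' inference with coverage and NSAF, secretion-signal enrichment (heuristic
#' predictor on each expressed transcript's longest ORF), and GO term
#' enrichment of the identified set against the expressed population. When
#' the input is a scenario with truth, recovery (sensitivity/precision of the
#' planted venom set, planted-enriched-term recall) is scored. Reruns with
#' the same inputs are deterministic: no stage draws random numbers.
#'
#' @param x A \code{\linkS4class{VenomScenario}}, or a list with paths
#'   \code{fasta}, \code{counts}, \code{peptides}, and optionally
#'   \code{go_map} (as written by \code{\link{writeScenario}}).
#' @param config A \code{\link{pipelineConfig}}.
#' @return A \code{\linkS4class{VenomReport}}.
#' @export
runPipeline <- function(x, config = pipelineConfig()) {
  if (methods::is(x, "VenomScenario")) {
    transcripts <- x@transcripts
    countTable <- x@countTable
    peptides <- x@peptides
    goMap <- x@goMap
    truth <- x@truth
  } else {
    need <- c("fasta", "counts", "peptides")
    if (!all(need %in% names(x)))
      stop("input error: need paths ", paste(need, collapse = ", "),
           call. = FALSE)
    missing <- !vapply(x[need], file.exists, logical(1))
    if (any(missing))
      stop("input error: missing file(s): ",
           paste(unlist(x[need])[missing], collapse = ", "), call. = FALSE)
    transcripts <- readTranscripts(x$fasta)
    countTable <- readCountTable(x$counts)
    peptides <- readPeptides(x$peptides)
    goMap <- if (!is.null(x$go_map)) readGoMap(x$go_map) else list()
    truth <- NULL
  }

  ## quantify and filter
  transcripts <- estimateTpm(transcripts, countTable, config$quant)
  stats_initial <- assemblyStats(transcripts, config$quant$minReportLength)
  flt <- filterExpressed(transcripts, config$quant$tpmThreshold)
  expressed <- flt$kept
  stats_filtered <- assemblyStats(expressed, config$quant$minReportLength)
  assembly <- cbind(data.frame(set = c("initial", "expression_filtered"),
                               stringsAsFactors = FALSE),
                    rbind(stats_initial, stats_filtered))
  assembly$percent_of_initial <- c(NA_integer_,
                                   reportPercent(flt$n_kept, flt$n_total))

  ## search database
  db <- buildSearchDatabase(expressed, minAaLen = config$minOrfLen)

  ## peptide cascade
  kept <- filterPeptides(peptides, config$filter)
  mapping <- if (length(expressed) > 0 && nrow(kept) > 0)
    mapPeptides(kept, db, collapseIl = config$filter$collapseIl)
  else list(matches = data.frame(peptide = character(),
                                 transcript_id = character()),
            unmatched = character(0))
  ids <- inferProteins(mapping, kept, db, config$filter)
  summ <- spectralSummary(ids, nInitialPeptides = nrow(peptides),
                          nKeptPeptides = nrow(kept))
  pep_block <- list(n_initial = nrow(peptides), n_kept = nrow(kept),
                    retained_percent = reportPercent(nrow(kept),
                                                     nrow(peptides)),
                    n_unmatched = length(mapping$unmatched))

  ## secretion signals on the longest ORF of every expressed transcript
  signal <- list()
  if (length(expressed) > 0) {
    lo <- longestOrf(expressed)
    preds <- predictSignal(stats::setNames(lo$sequence, lo$transcript_id))
    venom_ids <- ids$transcript_id
    is_venom <- preds$protein_id %in% venom_ids
    k1 <- sum(preds$call[is_venom])
    n1 <- sum(is_venom)
    if (config$bodyConvention == "all_minus_venom") {
      k2 <- sum(preds$call[!is_venom])
      n2 <- sum(!is_venom)
    } else {
      k2 <- sum(preds$call)
      n2 <- nrow(preds)
    }
    chisq <- if (n1 > 0 && n2 > 0 && (k1 + k2) > 0 && (k1 + k2) < (n1 + n2))
      signalEnrichment(k1, n1, k2, n2)
    else list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    signal <- list(venom_k = k1, venom_n = n1,
                   venom_percent = reportPercent(k1, max(n1, 1L)),
                   body_k = k2, body_n = n2,
                   body_percent = reportPercent(k2, max(n2, 1L)),
                   body_convention = config$bodyConvention,
                   chisq = chisq,
                   predictions = preds)
  }

  ## GO enrichment of identifications against the expressed population
  enrichment <- data.frame()
  if (length(goMap) > 0 && nrow(ids) > 0) {
    population <- transcriptIds(expressed)
    study <- intersect(ids$transcript_id, population)
    enrichment <- enrichTerms(study, population, goMap,
                              alpha = config$alpha)
  }

  ## recovery against planted truth
  recovery <- list()
  if (!is.null(truth)) {
    venom_true <- names(truth$label)[truth$label == "venom"]
    found <- ids$transcript_id
    tp <- length(intersect(found, venom_true))
    recovery <- list(
      sensitivity = if (length(venom_true)) tp / length(venom_true) else NA_real_,
      precision = if (length(found)) tp / length(found) else NA_real_,
      n_true = length(venom_true), n_found = length(found),
      enriched_term_recall =
        if (length(truth$enriched_terms) && nrow(enrichment) > 0)
          mean(truth$enriched_terms %in%
                 enrichment$term_id[enrichment$significant])
        else NA_real_)
  }

  new("VenomReport",
      assembly = assembly,
      peptides = pep_block,
      identifications = ids,
      summary = summ,
      signal = signal,
      enrichment = enrichment,
      recovery = recovery,
      provenance = list(
        config = unclass(config),
        seed = if (!is.null(truth)) x@config$seed else NA_integer_,
        package_version = as.character(utils::packageVersion("proteovenom")),
        timestamp = NA))
}
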