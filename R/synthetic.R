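# Ground-truthed synthetic scenario generator: transcriptome (expressed genes
# plus low-expression artifact contigs), read counts, tryptic peptide tables,
# planted secretion signals, GO annotations with planted enriched terms, and
# optional homology E-value tables.

#' Scenario configuration
#'
#' Defaults are a desk-scale mimicry of the real study: a few thousand
#' expressed genes, a small venom subset whose proteins dominate the peptide
#' pool (about 20 peptides per venom protein), a large population of
#' low-expression artifact contigs that the TPM filter must remove,
#' secretion signals planted on 35\% of venom versus 5\% of body proteins,
#' and a handful of GO terms enriched in the venom set.
#'
#' @param seed Integer seed; the whole scenario is a deterministic function
#'   of (config, seed).
#' @param nBodyGenes,nVenomGenes,nArtifactContigs Class sizes.
#' @param transcriptLengthMeanlog,transcriptLengthSdlog Lognormal parameters
#'   of gene transcript length in bp (defaults give a median near 1400 bp,
#'   the scale of an expression-filtered assembly).
#' @param expressionMeanlog,expressionSdlog Lognormal parameters of true gene
#'   abundance (arbitrary scale; normalized to TPM).
#' @param artifactTpmCeiling Artifact contigs receive read counts placing
#'   their TPM strictly below this ceiling (default 0.5, safely under the
#'   1-TPM expression filter).
#' @param peptidesPerVenomProtein Expected distinct peptides sampled per
#'   venom protein (Poisson mean).
#' @param contaminantPeptideFraction Expected fraction of peptide rows that
#'   are contaminants (digestion enzymes, keratin and similar; a free
#'   parameter of the generator, not an observed quantity).
#' @param trueProbAlpha,trueProbBeta Beta parameters of true-peptide
#'   identification probabilities (default Beta(8,2): most survive the >0.5
#'   filter).
#' @param noiseProbAlpha,noiseProbBeta Beta parameters of contaminant-peptide
#'   probabilities (default Beta(2,8): most are filtered out).
#' @param signalRateVenom,signalRateBody Planting rates of secretion signals.
#' @param nGoTerms,nEnrichedTerms,enrichmentOdds GO annotation structure:
#'   total terms, number planted as venom-enriched, and the odds ratio of
#'   term membership for venom versus body genes.
#' @param totalReads Total sequenced reads distributed over gene transcripts.
#' @param digestMinLen,digestMaxLen Tryptic peptide length window retained by
#'   the in-silico digest.
#' @return A validated list of class \code{ScenarioConfig}.
#' @export
scenarioConfig <- function(seed = 1L,
                           nBodyGenes = 2000L,
                           nVenomGenes = 50L,
                           nArtifactContigs = 1000L,
                           transcriptLengthMeanlog = log(1400),
                           transcriptLengthSdlog = 0.4,
                           expressionMeanlog = 3,
                           expressionSdlog = 1.5,
                           artifactTpmCeiling = 0.5,
                           peptidesPerVenomProtein = 20,
                           contaminantPeptideFraction = 0.05,
                           trueProbAlpha = 8, trueProbBeta = 2,
                           noiseProbAlpha = 2, noiseProbBeta = 8,
                           signalRateVenom = 0.35,
                           signalRateBody = 0.05,
                           nGoTerms = 50L,
                           nEnrichedTerms = 3L,
                           enrichmentOdds = 8,
                           totalReads = 2e6,
                           digestMinLen = 5L,
                           digestMaxLen = 35L) {
  cfg <- list(seed = as.integer(seed),
              nBodyGenes = as.integer(nBodyGenes),
              nVenomGenes = as.integer(nVenomGenes),
              nArtifactContigs = as.integer(nArtifactContigs),
              transcriptLengthMeanlog = transcriptLengthMeanlog,
              transcriptLengthSdlog = transcriptLengthSdlog,
              expressionMeanlog = expressionMeanlog,
              expressionSdlog = expressionSdlog,
              artifactTpmCeiling = artifactTpmCeiling,
              peptidesPerVenomProtein = peptidesPerVenomProtein,
              contaminantPeptideFraction = contaminantPeptideFraction,
              trueProbAlpha = trueProbAlpha, trueProbBeta = trueProbBeta,
              noiseProbAlpha = noiseProbAlpha, noiseProbBeta = noiseProbBeta,
              signalRateVenom = signalRateVenom,
              signalRateBody = signalRateBody,
              nGoTerms = as.integer(nGoTerms),
              nEnrichedTerms = as.integer(nEnrichedTerms),
              enrichmentOdds = enrichmentOdds,
              totalReads = totalReads,
              digestMinLen = as.integer(digestMinLen),
              digestMaxLen = as.integer(digestMaxLen))
  counts <- c("nBodyGenes", "nVenomGenes", "nArtifactContigs", "nGoTerms",
              "nEnrichedTerms")
  if (any(unlist(cfg[counts]) < 0))
    stop("counts must be non-negative", call. = FALSE)
  props <- c("contaminantPeptideFraction", "signalRateVenom",
             "signalRateBody")
  if (any(unlist(cfg[props]) < 0 | unlist(cfg[props]) > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (any(unlist(cfg[c("trueProbAlpha", "trueProbBeta", "noiseProbAlpha",
                       "noiseProbBeta")]) <= 0))
    stop("Beta parameters must be positive", call. = FALSE)
  if (cfg$nEnrichedTerms > cfg$nGoTerms)
    stop("nEnrichedTerms cannot exceed nGoTerms", call. = FALSE)
  if (cfg$nVenomGenes == 0 && cfg$contaminantPeptideFraction > 0)
    stop("configuration error: contaminant peptides requested but no venom ",
         "genes to scale them against", call. = FALSE)
  structure(cfg, class = "ScenarioConfig")
}

#' In-silico tryptic digest
#'
#' Cleaves a protein after every K or R not followed by P (trypsin
#' specificity) and returns the fragments within the requested length window.
#' The concatenation of all fragments before length filtering reconstructs
#' the protein.
#'
#' @param protein Amino-acid string over the 20-letter alphabet (no stop
#'   symbol).
#' @param minLen,maxLen Length window of retained peptides.
#' @return Character vector of peptides, in protein order.
#' @examples
#' digestProtein("AAKGG", minLen = 1)    # "AAK" "GG"
#' digestProtein("AAKPGG", minLen = 1)   # "AAKPGG" (no cleavage before P)
#' @export
digestProtein <- function(protein, minLen = 1L, maxLen = Inf) {
  stopifnot(length(protein) == 1L, minLen >= 1)
  .checkProtein(protein)
  cuts <- gregexpr("(?<=[KR])(?!P)", protein, perl = TRUE)[[1]]
  if (cuts[1L] == -1L) cuts <- integer(0)
  # cut positions are the first residue of the next fragment
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, nchar(protein))
  keep <- starts <= ends
  frags <- substring(protein, starts[keep], ends[keep])
  frags[nchar(frags) >= minLen & nchar(frags) <= maxLen]
}

# codon sets per amino acid, standard code, stops excluded
.codonsByAa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_STANDARD]
}

# Back-translate proteins into CDS nucleotide strings, sampling codons
# uniformly per residue. Vectorized over the whole residue pool.
.backTranslate <- function(proteins, codons) {
  res <- strsplit(proteins, "", fixed = TRUE)
  all_res <- unlist(res, use.names = FALSE)
  chosen <- character(length(all_res))
  for (aa in unique(all_res)) {
    pos <- which(all_res == aa)
    cod <- codons[[aa]]
    chosen[pos] <- cod[sample.int(length(cod), length(pos), replace = TRUE)]
  }
  grp <- rep(seq_along(proteins), lengths(res))
  vapply(split(chosen, grp), paste, character(1), collapse = "")
}

.randomNt <- function(n) {
  vapply(n, function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
}

.randomProtein <- function(nResidues) {
  paste(sample(names(AA_FREQS), nResidues, replace = TRUE, prob = AA_FREQS),
        collapse = "")
}

# Construct one signal peptide recognized by the built-in heuristic:
# M + K/R + hydrophobic core (11-16 of L/V/I/F) + small -3/-1 cleavage motif.
# The mature protein starts immediately after; the cleavage position equals
# nchar(signal) + 1 and is provably the first site the heuristic accepts.
.makeSignal <- function() {
  core_len <- sample(11:16, 1L)
  paste0("M",
         sample(c("K", "R"), 1L),
         paste(sample(c("L", "V", "I", "F"), core_len, replace = TRUE),
               collapse = ""),
         sample(c("A", "S", "G"), 1L),
         sample(names(AA_FREQS), 1L, prob = AA_FREQS),
         sample(c("A", "S", "G"), 1L))
}

#' Generate a ground-truthed scenario
#'
#' Builds a complete synthetic data set: gene transcripts each carrying a
#' valid ORF (start codon, in-frame upstream stop, no internal stops, stop
#' codon), low-expression artifact contigs guaranteed below the artifact TPM
#' ceiling, an identified-peptide table of in-silico tryptic fragments of the
#' venom proteins plus contaminant peptides, planted N-terminal secretion
#' signals (venom and body proteins at their configured rates; proteins
#' without a planted signal are rejection-sampled so the heuristic calls them
#' negative, keeping the planted truth unambiguous), GO annotations with
#' planted venom-enriched terms, and synthetic homology E-value tables.
#' Deterministic: the same (config, seed) yields byte-identical outputs.
#'
#' @param config A \code{\link{scenarioConfig}}.
#' @param seed Optional integer overriding \code{config$seed}.
#' @return A \code{\linkS4class{VenomScenario}}. Its \code{truth} list holds
#'   \code{label} (venom/body/artifact per transcript), \code{abundance}
#'   (true TPM; artifact entries are their target TPM), \code{signal}
#'   (data.frame: transcript_id, planted flag, cleavage position),
#'   \code{peptide_origin} (per peptide row: source transcript id or
#'   \code{"contaminant"}), \code{enriched_terms}.
#' @export
simulateScenario <- function(config = scenarioConfig(), seed = NULL) {
  stopifnot(inherits(config, "ScenarioConfig"))
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))
  codons <- .codonsByAa()

  nv <- config$nVenomGenes
  nb <- config$nBodyGenes
  na_ <- config$nArtifactContigs
  ng <- nv + nb
  n_all <- ng + na_
  ids <- sprintf("contig_%05d", seq_len(n_all))
  label <- rep(c("venom", "body", "artifact"), c(nv, nb, na_))
  names(label) <- ids

  ## --- gene transcripts -------------------------------------------------
  gene_seq <- character(ng)
  gene_len <- integer(ng)
  planted <- logical(ng)
  cleavage <- rep(NA_integer_, ng)
  proteins <- character(ng)
  if (ng > 0) {
    L <- pmin(pmax(round(stats::rlnorm(ng, config$transcriptLengthMeanlog,
                                       config$transcriptLengthSdlog)),
                   400L), 30000L)
    utr5 <- sample(33:90, ng, replace = TRUE)
    utr3 <- sample(50:200, ng, replace = TRUE)
    # protein length floor keeps the coding ORF longer than any chance
    # stop-free run in the five non-coding frames, so the longest ORF is the
    # protein and planted truth stays unambiguous
    aa_len <- pmax(180L, (L - utr5 - utr3) %/% 3L - 2L)
    # venom proteins must be able to furnish the configured peptide yield:
    # ~28 residues per observable tryptic peptide (in-window fragment rate
    # measured on the generator's residue composition)
    venom_floor <- as.integer(ceiling(28 * config$peptidesPerVenomProtein))
    if (nv > 0)
      aa_len[seq_len(nv)] <- pmax(aa_len[seq_len(nv)], venom_floor)
    rate <- ifelse(label[seq_len(ng)] == "venom", config$signalRateVenom,
                   config$signalRateBody)
    planted <- stats::runif(ng) < rate
    for (i in seq_len(ng)) {
      if (planted[i]) {
        sig <- .makeSignal()
        mature <- .randomProtein(aa_len[i] - nchar(sig))
        proteins[i] <- paste0(sig, mature)
        cleavage[i] <- nchar(sig) + 1L
      } else {
        for (try in seq_len(25L)) {
          proteins[i] <- paste0("M", .randomProtein(aa_len[i] - 1L))
          if (!.signalOne(substr(proteins[i], 1L, 45L))$call) break
        }
      }
    }
    cds <- .backTranslate(proteins, codons)
    stop_cod <- sample(c("TAA", "TAG", "TGA"), ng, replace = TRUE)
    up_stop <- sample(c("TAA", "TAG", "TGA"), ng, replace = TRUE)
    gene_seq <- paste0(.randomNt(utr5 - 3L), up_stop, cds, stop_cod,
                       .randomNt(utr3))
    gene_len <- nchar(gene_seq)
  }

  ## --- artifact contigs --------------------------------------------------
  art_len <- if (na_ > 0)
    pmin(pmax(round(stats::rlnorm(na_, log(350), 0.6)), 110L), 2500L)
  else integer(0)
  art_seq <- .randomNt(art_len)

  seqs <- Biostrings::DNAStringSet(c(gene_seq, art_seq))
  names(seqs) <- ids

  ## --- read counts -------------------------------------------------------
  gene_count <- numeric(ng)
  theta <- numeric(0)
  if (ng > 0) {
    theta <- stats::rlnorm(ng, config$expressionMeanlog,
                           config$expressionSdlog)
    frac <- theta * gene_len / sum(theta * gene_len)
    gene_count <- stats::rpois(ng, config$totalReads * frac)
  }
  art_target <- if (na_ > 0)
    stats::runif(na_, 0.02, 0.95) * config$artifactTpmCeiling
  else numeric(0)
  S_g <- if (ng > 0) sum(gene_count / gene_len) else 1
  art_count <- floor(art_target * 1e-6 * S_g * art_len)
  countTable <- data.frame(transcript_id = ids,
                           length_bp = c(gene_len, art_len),
                           count = c(gene_count, art_count),
                           ambiguity_group = NA_character_,
                           stringsAsFactors = FALSE)
  transcripts <- TranscriptomeSet(seqs,
                                  readCount = countTable$count)

  ## --- peptide table ------------------------------------------------------
  pep_rows <- list()
  if (nv > 0 && config$peptidesPerVenomProtein > 0) {
    for (i in seq_len(nv)) {
      src <- if (planted[i]) substr(proteins[i], cleavage[i],
                                    nchar(proteins[i])) else proteins[i]
      frags <- unique(digestProtein(src, config$digestMinLen,
                                    config$digestMaxLen))
      k <- min(stats::rpois(1L, config$peptidesPerVenomProtein),
               length(frags))
      if (k == 0) next
      sel <- frags[sample.int(length(frags), k)]
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        sequence = sel,
        probability = stats::rbeta(k, config$trueProbAlpha,
                                   config$trueProbBeta),
        charge = sample(c(1L, 2L, 3L), k, replace = TRUE,
                        prob = c(0.05, 0.60, 0.35)),
        spectral_count = 1L + stats::rpois(k, 1.5),
        origin = ids[i],
        stringsAsFactors = FALSE)
    }
  }
  peptides <- if (length(pep_rows)) do.call(rbind, pep_rows) else
    data.frame(sequence = character(), probability = numeric(),
               charge = integer(), spectral_count = integer(),
               origin = character(), stringsAsFactors = FALSE)
  f <- config$contaminantPeptideFraction
  if (f > 0 && nrow(peptides) > 0) {
    n_cont <- stats::rpois(1L, nrow(peptides) * f / (1 - f))
    if (n_cont > 0) {
      clen <- sample(6:20, n_cont, replace = TRUE)
      cont <- data.frame(
        sequence = vapply(clen, .randomProtein, character(1)),
        probability = stats::rbeta(n_cont, config$noiseProbAlpha,
                                   config$noiseProbBeta),
        charge = sample(c(1L, 2L, 3L), n_cont, replace = TRUE,
                        prob = c(0.30, 0.50, 0.20)),
        spectral_count = 1L + stats::rpois(n_cont, 0.3),
        origin = "contaminant",
        stringsAsFactors = FALSE)
      peptides <- rbind(peptides, cont)
    }
  }
  if (nrow(peptides) > 0) {
    ord <- sample.int(nrow(peptides))
    peptides <- peptides[ord, , drop = FALSE]
    rownames(peptides) <- NULL
  }
  peptide_origin <- peptides$origin
  peptides$origin <- NULL

  ## --- GO annotations ------------------------------------------------------
  goMap <- stats::setNames(rep(list(character(0)), ng), ids[seq_len(ng)])
  enriched_terms <- character(0)
  if (config$nGoTerms > 0 && ng > 0) {
    terms <- sprintf("GO:%07d", seq_len(config$nGoTerms))
    enriched_terms <- terms[seq_len(config$nEnrichedTerms)]
    base_rate <- stats::runif(config$nGoTerms, 0.02, 0.10)
    # planted enriched terms get a fixed, moderately common base rate so the
    # planted effect is detectable at the default study size (power by design)
    base_rate[seq_len(config$nEnrichedTerms)] <- 0.08
    member <- matrix(FALSE, nrow = ng, ncol = config$nGoTerms)
    is_venom <- label[seq_len(ng)] == "venom"
    for (t in seq_len(config$nGoTerms)) {
      q <- base_rate[t]
      p <- rep(q, ng)
      if (terms[t] %in% enriched_terms) {
        odds <- config$enrichmentOdds
        p[is_venom] <- q * odds / (1 + q * (odds - 1))
      }
      member[, t] <- stats::runif(ng) < p
    }
    goMap <- stats::setNames(
      lapply(seq_len(ng), function(i) terms[member[i, ]]),
      ids[seq_len(ng)])
  }

  ## --- homology E-values ---------------------------------------------------
  evalues <- data.frame(transcript_id = character(), subset = character(),
                        evalue = numeric(), stringsAsFactors = FALSE)
  if (ng > 0) {
    is_venom <- label[seq_len(ng)] == "venom"
    exp10 <- numeric(ng)
    exp10[is_venom] <- pmin(stats::rgamma(sum(is_venom), shape = 2,
                                          scale = 35), 180)
    exp10[!is_venom] <- pmin(stats::rgamma(sum(!is_venom), shape = 2,
                                           scale = 6), 180)
    evalues <- data.frame(transcript_id = ids[seq_len(ng)],
                          subset = ifelse(is_venom, "venom", "body"),
                          evalue = 10^(-exp10),
                          stringsAsFactors = FALSE)
  }

  truth <- list(
    label = label,
    abundance = stats::setNames(
      c(if (ng > 0) theta / sum(theta) * 1e6 else numeric(0), art_target),
      ids),
    signal = data.frame(transcript_id = ids[seq_len(ng)],
                        planted = planted,
                        cleavage_position = cleavage,
                        stringsAsFactors = FALSE),
    peptide_origin = peptide_origin,
    enriched_terms = enriched_terms)

  cfg <- unclass(config)
  cfg$seed <- as.integer(seed)
  new("VenomScenario", transcripts = transcripts, countTable = countTable,
      peptides = peptides, goMap = goMap, evalues = evalues, truth = truth,
      config = cfg)
}

#' Write a scenario to disk
#'
#' Materializes every pipeline input as the plain-text formats the loaders
#' consume: \code{transcripts.fasta}, \code{counts.tsv},
#' \code{peptides.tsv}, \code{go_map.tsv}, \code{evalues.tsv}, and the
#' ground truth as \code{truth.json}.
#'
#' @param scenario A \code{\linkS4class{VenomScenario}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "transcripts.fasta"),
             counts = file.path(dir, "counts.tsv"),
             peptides = file.path(dir, "peptides.tsv"),
             go_map = file.path(dir, "go_map.tsv"),
             evalues = file.path(dir, "evalues.tsv"),
             truth = file.path(dir, "truth.json"))
  writeTranscripts(scenario@transcripts, paths[["fasta"]])
  writeCountTable(scenario@countTable, paths[["counts"]])
  writePeptides(scenario@peptides, paths[["peptides"]])
  writeGoMap(scenario@goMap, paths[["go_map"]])
  utils::write.table(scenario@evalues, paths[["evalues"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- scenario@truth
  truth$label <- as.list(truth$label)
  truth$abundance <- as.list(truth$abundance)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(paths)
}
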