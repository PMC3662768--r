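# GO term over-representation analysis with Bonferroni correction.

.splitTerms <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) unique(trimws(v[nzchar(trimws(v))])))
}

#' Read a composed gene-to-GO map
#'
#' TSV with two columns: gene id and a semicolon-separated list of term ids
#' (which may be empty).
#'
#' @param file Path to the TSV (no header).
#' @return Named list: gene id to character vector of term ids.
#' @export
readGoMap <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[`, character(1), 1L)
  terms <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "",
                  character(1))
  stats::setNames(.splitTerms(terms), genes)
}

#' Write a composed gene-to-GO map
#'
#' @param map Named list, gene id to character vector of term ids.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeGoMap <- function(map, file) {
  writeLines(sprintf("%s\t%s", names(map),
                     vapply(map, paste, character(1), collapse = ";")), file)
  invisible(file)
}

#' Compose gene-to-family and family-to-term annotations
#'
#' Mirrors the two-step annotation route (protein families assigned to
#' genes, then a family-to-GO translation table): genes whose families lack a
#' translation get empty term sets. Both files are headerless TSVs; the
#' second column may hold a semicolon-separated list. Malformed rows (fewer
#' than one field) raise an error with the line number.
#'
#' @param geneFamilyFile TSV: gene id, semicolon-separated family ids.
#' @param familyTermFile TSV: family id, semicolon-separated term ids.
#' @return list with \code{map} (gene to terms), \code{families} (gene to
#'   families), and annotation counts \code{n_genes}, \code{n_with_family},
#'   \code{n_with_term} mirroring the annotation-fraction columns of the
#'   results table.
#' @export
loadAnnotations <- function(geneFamilyFile, familyTermFile) {
  readPairs <- function(file, what) {
    lines <- readLines(file)
    keep <- nzchar(lines)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(vapply(parts, function(p) length(p) < 1L || !nzchar(p[1L]),
                        logical(1)))
    if (length(bad))
      stop(sprintf("malformed %s row at line %d", what,
                   which(keep)[bad[1L]]), call. = FALSE)
    list(key = vapply(parts, `[`, character(1), 1L),
         val = .splitTerms(vapply(parts, function(p)
           if (length(p) >= 2L) p[2L] else "", character(1))))
  }
  gf <- readPairs(geneFamilyFile, "gene-family")
  ft <- readPairs(familyTermFile, "family-term")
  fam2term <- stats::setNames(ft$val, ft$key)
  families <- stats::setNames(gf$val, gf$key)
  map <- lapply(families, function(fams) {
    unique(unlist(fam2term[fams[fams %in% names(fam2term)]], use.names = FALSE))
  })
  map <- lapply(map, function(v) if (is.null(v)) character(0) else v)
  list(map = map,
       families = families,
       n_genes = length(families),
       n_with_family = sum(lengths(families) > 0),
       n_with_term = sum(lengths(map) > 0))
}

#' GO term over-representation test
#'
#' One-sided hypergeometric test of over-representation for every term
#' annotated in the population: with a study set of size n drawn from a
#' population of size N in which K genes carry the term and k study genes
#' carry it, \code{p_raw = P(X >= k)} for X hypergeometric(N, K, n).
#' Bonferroni correction multiplies by the number m of tested terms (terms
#' with K >= 1); a term is flagged significant iff
#' \code{p_bonferroni < alpha}. No GO hierarchy propagation is performed:
#' terms are compared exactly as given in the map.
#'
#' @param study Character vector of study gene ids (must be a subset of the
#'   population).
#' @param population Character vector of population gene ids.
#' @param annotation Named list (gene id to term ids) as from
#'   \code{\link{readGoMap}}, or the result of \code{\link{loadAnnotations}}.
#' @param alpha Significance level for the Bonferroni flag (default 0.05).
#' @return data.frame sorted by ascending \code{p_raw} with \code{term_id},
#'   \code{study_count}, \code{study_size}, \code{population_count},
#'   \code{population_size}, \code{p_raw}, \code{p_bonferroni},
#'   \code{significant}.
#' @export
enrichTerms <- function(study, population, annotation, alpha = 0.05) {
  if (is.list(annotation) && !is.null(annotation$map))
    annotation <- annotation$map
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population))
    stop("study set is not a subset of the population", call. = FALSE)
  if (length(population) == 0)
    stop("empty population", call. = FALSE)
  ann <- annotation[names(annotation) %in% population]
  pop_terms <- unlist(ann, use.names = FALSE)
  if (length(pop_terms) == 0)
    return(data.frame(term_id = character(), study_count = integer(),
                      study_size = integer(), population_count = integer(),
                      population_size = integer(), p_raw = numeric(),
                      p_bonferroni = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  K <- table(pop_terms)
  study_terms <- unlist(ann[names(ann) %in% study], use.names = FALSE)
  k <- table(factor(study_terms, levels = names(K)))
  N <- length(population)
  n <- length(study)
  m <- length(K)
  terms <- names(K)
  p_raw <- stats::phyper(as.numeric(k) - 1, as.numeric(K),
                         N - as.numeric(K), n, lower.tail = FALSE)
  res <- data.frame(term_id = terms,
                    study_count = as.integer(k),
                    study_size = n,
                    population_count = as.integer(K),
                    population_size = N,
                    p_raw = p_raw,
                    p_bonferroni = pmin(1, p_raw * m),
                    stringsAsFactors = FALSE)
  res$significant <- res$p_bonferroni < alpha
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
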