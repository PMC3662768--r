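# Shared constants and small helpers.

# The 20 standard amino acids, one-letter code.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average amino-acid composition of well-curated protein databases
# (UniProtKB/Swiss-Prot release statistics), used by the scenario generator.
AA_FREQS <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0672, G = 0.0707, H = 0.0227, I = 0.0591,
  L = 0.0965, K = 0.0580, M = 0.0241, F = 0.0386, P = 0.0474,
  S = 0.0663, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686
)

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Report a ratio as an integer percentage
#'
#' Percentages in report tables are rounded half away from zero to the
#' nearest integer, the convention used for all printed retention and
#' annotation percentages.
#'
#' @param numerator,denominator Non-negative numerics (vectorized).
#' @return Integer percentage(s); \code{NA} where the denominator is zero.
#' @examples
#' reportPercent(21625, 49972)  # 43
#' reportPercent(2686, 2917)    # 92
#' @export
reportPercent <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator) ||
              length(numerator) == 1L || length(denominator) == 1L)
  p <- 100 * numerator / denominator
  out <- ifelse(denominator == 0, NA_integer_,
                as.integer(sign(p) * floor(abs(p) + 0.5)))
  out
}

# Collapse isoleucine onto leucine: the two residues are mass-identical and
# indistinguishable by the mass spectrometer.
ilCollapse <- function(x) chartr("I", "L", x)

# Validate an amino-acid string over the 20-letter alphabet.
.checkProtein <- function(x, what = "protein") {
  bad <- grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains residues outside the 20-letter alphabet: %s",
                 what, paste(head(x[bad], 3L), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
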