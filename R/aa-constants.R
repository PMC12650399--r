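#' Amino-acid alphabet and background composition
#'
#' `AA20` is the 20-letter amino-acid alphabet in alphabetical one-letter
#' order. `swissprotFrequencies()` returns the average amino-acid composition
#' of the UniProtKB/Swiss-Prot database (release statistics), normalized to
#' sum to 1. This composition is the default background for random-peptide
#' sampling and for probability-logo statistics when no empirical background
#' window set is supplied.
#'
#' @return `swissprotFrequencies()`: a named numeric vector over [AA20]
#'   summing to 1.
#' @examples
#' sum(swissprotFrequencies())
#' swissprotFrequencies()[["E"]]  # glutamate, ~0.067
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA20
#' @export
swissprotFrequencies <- function() {
  # Swiss-Prot release-note composition table (percent), renormalized.
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.46, C = 1.38,
         Q = 3.93, E = 6.72, G = 7.07, H = 2.27, I = 5.91,
         L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.74,
         S = 6.64, T = 5.35, W = 1.10, Y = 2.92, V = 6.86)
  f <- f[AA20]
  f / sum(f)
}

# Pad character used outside protein termini in sequence windows; excluded
# from all frequency counts.
PAD_CHAR <- "_"

# One- <-> three-letter residue code maps (HGVS protein notation).
AA_THREE <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
              G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
              M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
              S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
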