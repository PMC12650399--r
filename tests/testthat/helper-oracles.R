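# Independent oracles, deliberately naive: direct tail summation for the
# binomial statistic and exhaustive subset enumeration for the
# hypergeometric test. They never share code with the implementation.

# P(K >= k) and P(K <= k) for K ~ Binomial(n, p), by explicit summation of
# choose(n, i) p^i (1-p)^(n-i) in log space.
bruteBinomTail <- function(k, n, p, upper = TRUE) {
  i <- if (upper) k:n else 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

bruteBinomHeight <- function(k, n, p) {
  if (k / n >= p) -log10(bruteBinomTail(k, n, p, upper = TRUE))
  else log10(bruteBinomTail(k, n, p, upper = FALSE))
}

# P(X >= k) for the hypergeometric by enumerating every n-subset of a
# universe 1..N in which 1..K are the annotated elements.
bruteHyperUpper <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Plain random 15-mers for tests that need ad-hoc window sets.
sampleBackgroundRawForTest <- function(n, freqs, radius = 7L) {
  vapply(seq_len(n), function(i) {
    paste(sample(names(freqs), 2L * radius + 1L, TRUE, freqs), collapse = "")
  }, character(1))
}

# Tiny hand-built protein set used across module tests.
toyProteins <- function() {
  # P2 is a membrane protein: luminal 1-10 (site S5, E7), TM 11-30,
  # cytoplasmic 31-40 (site S35, E37)
  p2 <- rep("M", 40L)
  p2[c(5L, 35L)] <- "S"
  p2[c(7L, 37L)] <- "E"
  newProteinSet(
    c(P1 = "MKTSAEQRLAAGGSSEQPL",          # soluble extracellular, site S4..E6
      P2 = paste(p2, collapse = ""),
      P3 = "AAASAEAAA",                    # cytosolic
      P4 = "GGGSGEGGG"),                   # non-classical secretion
    data.frame(
      accession = c("P1", "P2", "P3", "P4"),
      gene = c("G1", "G2", "G3", "G4"),
      compartments = c("extracellular region",
                       "Golgi lumen;cytosol",
                       "cytosol",
                       "extracellular space"),
      secretion_route = c("classical", "classical", "none", "non_classical"),
      stringsAsFactors = FALSE),
    data.frame(accession = "P2",
               start = c(1L, 11L, 31L),
               end = c(10L, 30L, 40L),
               side = c("luminal_or_extracellular", "transmembrane",
                        "cytoplasmic"),
               stringsAsFactors = FALSE))
}
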