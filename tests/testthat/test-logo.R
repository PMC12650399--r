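test_that("binomial heights equal closed-form extreme tails", {
  expect_equal(binomialHeight(10, 10, 0.05), -log10(0.05^10), tolerance = 1e-9)
  expect_equal(binomialHeight(0, 10, 0.5), log10(0.5^10), tolerance = 1e-9)
  # k exactly at the expectation: small non-negative height
  h <- binomialHeight(5, 100, 0.05)
  expect_gte(h, 0)
  expect_lte(h, -log10(0.5))
  expect_error(binomialHeight(3, 10, 0), "strictly inside")
  expect_error(binomialHeight(3, 10, 1), "strictly inside")
  expect_error(binomialHeight(11, 10, 0.5), "0 <= k <= n")
})

test_that("binomial heights match the brute-force summation oracle", {
  for (n in c(1:10, 25, 50, 117, 200)) {
    for (p in c(0.05, 0.3, 0.5, 0.9)) {
      k <- 0:n
      got <- binomialHeight(k, n, p)
      want <- vapply(k, bruteBinomHeight, numeric(1), n = n, p = p)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("height is monotone in n at fixed enrichment and antisymmetric at p = 0.5", {
  # fixed k/n above background: evidence accumulates with n
  ns <- c(20, 40, 80, 160)
  h <- binomialHeight(ns * 0.25, ns, 0.1)
  expect_true(all(diff(h) > 0))
  # antisymmetry at the median for odd n (no k == n/2 midpoint)
  n <- 31
  for (k in 0:n)
    expect_equal(binomialHeight(k, n, 0.5), -binomialHeight(n - k, n, 0.5),
                 tolerance = 1e-9)
})

test_that("Bonferroni threshold follows the closed form", {
  expect_equal(bonferroniThreshold(0.05, 14, 20), -log10(0.05 / 280),
               tolerance = 1e-12)
  expect_equal(bonferroniThreshold(0.05, 1, 1), -log10(0.05),
               tolerance = 1e-12)
  expect_equal(bonferroniThreshold(1 - 1e-12, 1, 1), 0, tolerance = 1e-9)
  expect_error(bonferroniThreshold(1.2, 14), "alpha")
})

test_that("count matrix tallies residues, excludes pads, reports center composition", {
  w <- c("AAAAAAASAEAAAAA", "CCCCCCCSCECCCCC")
  cm <- countMatrix(w)
  expect_identical(nWindows(cm), 2L)
  expect_equal(logoFreqs(cm)["E", "2"], 1.0)
  expect_identical(unname(logoCounts(cm)["S", "0"]), 2L)
  expect_identical(cm@centerComposition, c(S = 2L, T = 0L))
  # all-pad column: zero total, missing frequencies
  wp <- c("_______SAEAAAAA", "_______SCECCCCC")
  cmp <- countMatrix(wp)
  expect_identical(sum(logoCounts(cmp)[, "-7"]), 0L)
  expect_true(all(is.nan(logoFreqs(cmp)[, "-7"])))
  # column totals count only non-pad characters
  expect_equal(unname(colSums(logoCounts(cmp))[c("-7", "2")]), c(0, 2))
  expect_error(countMatrix(character(0)), "no windows")
})

test_that("frequency columns sum to one wherever the column is covered", {
  set.seed(7)
  w <- sampleBackground(simulationConfig(nBackgroundPeptides = 200, seed = 3))
  cm <- countMatrix(w)
  expect_equal(unname(colSums(logoFreqs(cm))), rep(1, 15), tolerance = 1e-12)
})

test_that("heights have the sign of freq minus background and flag planted signal", {
  set.seed(1)
  bg <- swissprotFrequencies()
  n <- 500
  w <- sampleBackgroundRawForTest(n, bg)
  substr(w, 8, 8) <- "S"
  substr(w, 10, 10) <- ifelse(runif(n) < 0.8, "E",
                              sample(setdiff(AA20, "E"), n, TRUE))
  lm <- logoHeights(countMatrix(w), bg)
  h <- logoHeightsMatrix(lm)
  f <- logoFreqs(lm)
  off0 <- colnames(h) != "0"
  sgn <- sign(h[, off0])
  dif <- sign(f[, off0] - bg)
  expect_true(all(sgn == dif | sgn == 0 | dif == 0))
  top <- significantCells(lm)
  expect_identical(top$position[1], 2L)
  expect_identical(top$residue[1], "E")
})

test_that("a background sample analysed against itself shows nothing significant", {
  cfg <- simulationConfig(nBackgroundPeptides = 400, seed = 11)
  w <- sampleBackground(cfg)
  lm <- logoHeights(countMatrix(w), w)  # background estimated from the same set
  expect_identical(nrow(significantCells(lm)), 0L)
})

test_that("stratified comparison shares one background and is stable for identical strata", {
  cfg <- simulationConfig(nBackgroundPeptides = 300, seed = 5)
  w <- sampleBackground(cfg)
  res <- stratifiedCompare(list(a = w[1:100], b = w[1:100]), w)
  expect_identical(logoCounts(res$a), logoCounts(res$b))
  expect_identical(logoHeightsMatrix(res$a), logoHeightsMatrix(res$b))
  expect_identical(logoBackground(res$a), logoBackground(res$b))
  expect_error(stratifiedCompare(list(), w), "at least one")
})

test_that("logo matrices round-trip to TSV and JSON summaries", {
  dir <- withr::local_tempdir()
  w <- syntheticValidatedWindows(2, n = 60)
  lm <- logoHeights(countMatrix(w), swissprotFrequencies())
  paths <- writeLogoMatrix(lm, file.path(dir, "logo"))
  counts <- read.delim(paths[1], check.names = FALSE)
  expect_identical(counts$residue, AA20)
  expect_equal(unname(as.matrix(counts[, -1])), unname(logoCounts(lm)))
  js <- jsonlite::read_json(paths[4])
  expect_identical(js$n_windows, 60L)
})

test_that("MSA motif conservation maps reference coordinates through gaps", {
  msa <- c(ref = "MK-TSAE-QR", a = "MKATSAEAQR", b = "MKATSAEA--",
           c = "MKAT-AAAQR")
  # ref ungapped: M1 K2 T3 S4 A5 E6 Q7 R8; site S4 -> column 5, +2 E6 -> col 7
  out <- msaMotifConservation(msa, "ref", 4)
  expect_equal(unname(out["fraction_S_conserved"]), 3 / 3)  # c is gapped there
  expect_equal(unname(out["fraction_E_plus2_conserved"]), 3 / 4)
  # matchST counts threonine centers too
  msa2 <- c(ref = "SAE", a = "TAE", b = "AAE", c = "SAE")
  expect_equal(unname(msaMotifConservation(msa2, "ref", 1)[1]), 0.5)
  expect_equal(unname(msaMotifConservation(msa2, "ref", 1,
                                           matchST = TRUE)[1]), 0.75)
  # no +2 column for a site at the reference end
  expect_error(msaMotifConservation(msa2, "ref", 3), "no \\+2 residue")
  expect_error(msaMotifConservation(msa2, "nope", 1), "not found")
})
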