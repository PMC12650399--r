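test_that("generation is deterministic given the seed", {
  cfg <- simulationConfig(nProteins = 30, nSitesSecretory = 40,
                          nSitesCytosol = 20, nSitesNuclear = 10,
                          nBackgroundPeptides = 50, nVariants = 10, seed = 5)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(as.character(sequences(a$proteins)),
                   as.character(sequences(b$proteins)))
  expect_identical(a$sites, b$sites)
  expect_identical(a$background, b$background)
  expect_identical(a$variants, b$variants)
  # and byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeDataset(a, d1); writeDataset(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("forcing the +2 glutamate plants it in every secretory serine window", {
  cfg <- simulationConfig(nProteins = 40, nSitesSecretory = 50,
                          nSitesCytosol = 0, nSitesNuclear = 0,
                          fEplus2 = 1.0, serFraction = 1.0,
                          nBackgroundPeptides = 1, nVariants = 0, seed = 1)
  ds <- simulateDataset(cfg)
  win <- extractWindows(ds$sites, ds$proteins)
  expect_identical(nrow(win), 50L)
  expect_true(all(substr(win$window, 8, 8) == "S"))
  expect_true(all(substr(win$window, 10, 10) == "E"))
})

test_that("with planting at the background rate the E@+2 fraction stays at background", {
  bg <- swissprotFrequencies()
  cfg <- simulationConfig(nProteins = 60, nSitesSecretory = 400,
                          nSitesCytosol = 0, nSitesNuclear = 0,
                          fEplus2 = unname(bg["E"]), serFraction = 1.0,
                          nBackgroundPeptides = 1, nVariants = 0, seed = 2)
  ds <- simulateDataset(cfg)
  win <- extractWindows(ds$sites, ds$proteins)
  k <- sum(substr(win$window, 10, 10) == "E")
  ci <- stats::binom.test(k, nrow(win), conf.level = 0.99)$conf.int
  expect_gte(bg[["E"]], ci[1])
  expect_lte(bg[["E"]], ci[2])
})

test_that("background sampling matches its generating frequencies", {
  unif <- setNames(rep(1 / 20, 20), AA20)
  cfg <- simulationConfig(backgroundFreqs = unif,
                          nBackgroundPeptides = 10000, seed = 3)
  w <- sampleBackground(cfg)
  expect_identical(length(w), 10000L)
  expect_false(any(grepl("_", w, fixed = TRUE)))
  ch <- unlist(strsplit(w, ""))
  freq <- table(factor(ch, levels = AA20)) / length(ch)
  sigma <- sqrt(0.05 * 0.95 / length(ch))
  expect_true(all(abs(freq - 0.05) < 3 * sigma + 1e-12))
  # degenerate composition
  spike <- setNames(c(1, rep(0, 19)), AA20)  # all alanine
  w1 <- sampleBackground(simulationConfig(backgroundFreqs = spike,
                                          nBackgroundPeptides = 3, seed = 1))
  expect_identical(unique(w1), strrep("A", 15))
  w2 <- sampleBackground(simulationConfig(nBackgroundPeptides = 1, seed = 1))
  expect_identical(length(w2), 1L)
})

test_that("infeasible site demands raise an error", {
  cfg <- simulationConfig(nProteins = 3, meanProteinLength = 40,
                          nSitesSecretory = 5000, nBackgroundPeptides = 1,
                          seed = 1)
  expect_error(simulateDataset(cfg), "infeasible|no proteins")
})

test_that("membrane proteins carry alternating topology and variants match sequences", {
  ds <- simulateDataset(simulationConfig(
    nProteins = 80, nSitesSecretory = 100, nSitesCytosol = 40,
    nSitesNuclear = 20, membraneFraction = 0.5, nBackgroundPeptides = 1,
    nVariants = 40, seed = 9))
  topo <- topologySegments(ds$proteins)
  expect_gt(nrow(topo), 0)
  for (acc in unique(topo$accession)) {
    seg <- topo[topo$accession == acc, ]
    seg <- seg[order(seg$start), ]
    expect_true("transmembrane" %in% seg$side)
    expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))  # non-overlap
    expect_true(all(seg$side[-1] != seg$side[-nrow(seg)])) # alternating
  }
  # every variant's reference residue matches the protein sequence
  seqs <- as.character(sequences(ds$proteins))
  ref <- substr(seqs[ds$variants$accession], ds$variants$protein_position,
                ds$variants$protein_position)
  expect_identical(unname(ref), ds$variants$ref_aa)
})

test_that("the motif-fraction estimate recovers the planted rate across seeds", {
  hitsCI <- 0L
  nSeeds <- 100L
  f <- 0.8
  for (s in seq_len(nSeeds)) {
    ds <- simulateDataset(simulationConfig(
      nProteins = 70, meanProteinLength = 300, nSitesSecretory = 500,
      nSitesCytosol = 0, nSitesNuclear = 0, fEplus2 = f, serFraction = 1.0,
      nBackgroundPeptides = 1, nVariants = 0, seed = 1000 + s))
    win <- extractWindows(ds$sites, ds$proteins)
    cm <- countMatrix(win$window)
    k <- logoCounts(cm)["E", "2"]
    ci <- stats::binom.test(k, nWindows(cm))$conf.int
    if (f >= ci[1] && f <= ci[2]) hitsCI <- hitsCI + 1L
  }
  expect_gte(hitsCI, 90L)
})
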