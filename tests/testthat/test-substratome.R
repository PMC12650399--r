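toySites <- function() {
  data.frame(
    accession = c("P1", "P2", "P2", "P3", "P4", "P1", "ZZ"),
    position = c(4L, 5L, 35L, 4L, 4L, 15L, 1L),
    residue = c("S", "S", "S", "S", "S", "S", "S"),
    evidence = c("validated_direct", "large_scale", "large_scale",
                 "large_scale", "large_scale", "large_scale", "large_scale"),
    source_compartment_terms = "",
    stringsAsFactors = FALSE)
}

test_that("the cascade applies rules in order and reports first failing reason", {
  res <- applyFilters(toySites(), toyProteins())
  # P1@4: soluble extracellular Ser with E at +2 -> kept
  expect_true("P1" %in% res$kept$accession &&
                4L %in% res$kept$position[res$kept$accession == "P1"])
  rej <- setNames(res$rejected$reason,
                  paste(res$rejected$accession, res$rejected$position))
  # P2@5 luminal segment -> kept; P2@35 cytoplasmic segment -> topology
  expect_true(5L %in% res$kept$position[res$kept$accession == "P2"])
  expect_identical(unname(rej[["P2 35"]]), "topology")
  # P3: cytosol-only protein -> compartment
  expect_identical(unname(rej[["P3 4"]]), "compartment")
  # P4: non-classical secretion -> secretion_route
  expect_identical(unname(rej[["P4 4"]]), "secretion_route")
  # P1@15: S with no E at +2 (+2 is Q) -> motif
  expect_identical(unname(rej[["P1 15"]]), "motif")
  # unknown accession -> unmapped, not a crash
  expect_identical(unname(rej[["ZZ 1"]]), "unmapped")
})

test_that("threonine centers are rejected under the default config but kept with S_or_T", {
  ps <- newProteinSet(
    c(Q1 = "AAAAAATAEAAAAAA"),
    data.frame(accession = "Q1", gene = "G", compartments = "Golgi lumen",
               secretion_route = "classical"))
  sites <- data.frame(accession = "Q1", position = 7L, residue = "T",
                      evidence = "large_scale",
                      source_compartment_terms = "")
  strict <- applyFilters(sites, ps)
  expect_identical(strict$rejected$reason, "center_residue")
  loose <- applyFilters(sites, ps, filterConfig(requireCenter = "S_or_T"))
  expect_identical(nrow(loose$kept), 1L)
})

test_that("a site with no +2 residue cannot match the motif", {
  ps <- newProteinSet(
    c(Q1 = "AAAAAAAAAAAAAS"),  # serine at the penultimate... last position
    data.frame(accession = "Q1", gene = "G", compartments = "Golgi lumen",
               secretion_route = "classical"))
  sites <- data.frame(accession = "Q1", position = 14L, residue = "S",
                      evidence = "large_scale",
                      source_compartment_terms = "")
  res <- applyFilters(sites, ps)
  expect_identical(res$rejected$reason, "motif")
})

test_that("an annotated phospho-serine at +2 can satisfy the acidic requirement", {
  ps <- newProteinSet(
    c(Q1 = "AAAAAASASAAAAAA"),  # S7 with S9 at +2
    data.frame(accession = "Q1", gene = "G", compartments = "Golgi lumen",
               secretion_route = "classical"))
  sites <- data.frame(accession = "Q1", position = c(7L, 9L), residue = "S",
                      evidence = "large_scale",
                      source_compartment_terms = "")
  strict <- applyFilters(sites, ps)
  expect_true(all(c("motif") %in% strict$rejected$reason))
  loose <- applyFilters(sites, ps, filterConfig(allowPSerPlus2 = TRUE))
  expect_true(7L %in% loose$kept$position)  # S9 is itself a phosphosite
})

test_that("kept entries satisfy the motif contract and are deduplicated", {
  sites <- rbind(toySites(), toySites())  # duplicates
  res <- applyFilters(sites, toyProteins())
  expect_false(any(duplicated(res$kept[c("accession", "position")])))
  expect_identical(nrow(res$kept) + nrow(res$rejected),
                   nrow(unique(toySites()[c("accession", "position")])))
  expect_true(all(res$kept$residue == "S"))
  expect_true(all(substr(res$kept$window, 10, 10) == "E"))
  expect_true(all(table(paste(res$rejected$accession,
                              res$rejected$position)) == 1))
})

test_that("novelty comparison counts overlaps at site and protein level", {
  put <- data.frame(accession = c("A", "A", "B", "C"),
                    position = c(10L, 20L, 5L, 7L))
  nov <- compareToValidated(put,
                            data.frame(accession = "A", position = 10L),
                            validatedProteins = c("A"))
  expect_identical(nov$site_novel, 3L)
  expect_identical(nov$site_novel_pct, 75.0)
  expect_identical(nov$protein_novel, 2L)
  # identity: putative == validated gives zero novel
  nov2 <- compareToValidated(put, put)
  expect_identical(nov2$site_novel, 0L)
  expect_identical(nov2$site_novel_pct, 0)
})

test_that("summaries report counts, compartment tallies and the E@+2 fraction", {
  res <- applyFilters(toySites(), toyProteins())
  s <- summarizeSubstratome(res$kept)
  expect_identical(s$n_sites, nrow(res$kept))
  expect_identical(s$n_proteins, length(unique(res$kept$accession)))
  expect_identical(s$e_plus2_fraction, 1)
  empty <- summarizeSubstratome(res$kept[0, ])
  expect_identical(empty$n_sites, 0L)
  expect_identical(empty$n_proteins, 0L)
})
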