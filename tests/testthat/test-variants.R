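test_that("the packaged motif fixture yields the expected clinical hit table", {
  fx <- syntheticVariantFixture(1)
  sub <- applyFilters(fx$sites, fx$proteins)$kept
  hits <- screenVariants(fx$variants, sub, proteins = fx$proteins)
  byGene <- split(hits, hits$gene)
  # transthyretin-like: the Ser72 variant plus four +2 glutamate variants
  expect_identical(sum(byGene$TTR$role == "S_center"), 1L)
  expect_identical(byGene$TTR$hgvs_p[byGene$TTR$role == "S_center"],
                   "p.Ser72Pro")
  expect_setequal(byGene$TTR$hgvs_p[byGene$TTR$role == "E_plus2"],
                  c("p.Glu74Ala", "p.Glu74Gly", "p.Glu74Lys", "p.Glu74Gln"))
  expect_identical(byGene$PCSK9$hgvs_p, "p.Ser47Cys")
  expect_identical(byGene$PCSK9$role, "S_center")
  expect_identical(byGene$VWF$hgvs_p, "p.Ser1517Arg")
  expect_identical(byGene$VWF$role, "S_center")
  # only pathogenic/likely-pathogenic classes reported: three genes, not four
  expect_setequal(names(byGene), c("TTR", "PCSK9", "VWF"))
  # conflicting submissions are flagged, not resolved
  expect_true(all(hits$conflict[hits$hgvs_p %in%
                                  c("p.Glu74Lys", "p.Glu74Gln")]))
  expect_false(any(hits$conflict[hits$hgvs_p == "p.Ser72Pro"]))
})

test_that("screening with other classes selects only those records", {
  fx <- syntheticVariantFixture(1)
  sub <- applyFilters(fx$sites, fx$proteins)$kept
  unc <- screenVariants(fx$variants, sub, classes = "uncertain",
                        proteins = fx$proteins)
  expect_true(all(unc$classification == "uncertain"))
  expect_true("SYNX1" %in% unc$gene)
})

test_that("off-motif variants produce no hits and unmatched variants are counted", {
  fx <- syntheticVariantFixture(1)
  sub <- applyFilters(fx$sites, fx$proteins)$kept
  v <- data.frame(gene = c("TTR", "XX"), accession = c("TTR_SYN", "XX"),
                  hgvs_p = c("p.Ala73Gly", "p.Ser5Ala"),
                  classification = "pathogenic", condition = "",
                  stringsAsFactors = FALSE)
  v <- cbind(v[1:5], parseHgvsP(v$hgvs_p))
  hits <- screenVariants(v, sub)
  expect_identical(nrow(hits), 0L)          # +1 position is not screened
  expect_identical(attr(hits, "n_unmatched"), 1L)
})

test_that("reference-residue mismatches are flagged and excluded from the report", {
  dir <- withr::local_tempdir()
  fx <- syntheticVariantFixture(1)
  sub <- applyFilters(fx$sites, fx$proteins)$kept
  bad <- fx$variants[fx$variants$hgvs_p == "p.Ser72Pro", ]
  bad$hgvs_p <- "p.Ala72Pro"; bad$ref_aa <- "A"
  hits <- screenVariants(bad, sub, proteins = fx$proteins)
  expect_true(all(hits$ref_mismatch))
  rep <- writeHitReport(hits, file.path(dir, "hits.tsv"))
  expect_identical(nrow(rep), 0L)
  # zero hits still writes a header-only file
  lines <- readLines(file.path(dir, "hits.tsv"))
  expect_identical(length(lines), 1L)
  expect_match(lines[1], "^gene\taccession\tvariant")
})

test_that("screening agrees with a brute-force double loop and is order-invariant", {
  set.seed(12)
  ds <- simulateDataset(simulationConfig(
    nProteins = 40, nSitesSecretory = 60, nSitesCytosol = 20,
    nSitesNuclear = 10, nBackgroundPeptides = 1, nVariants = 40, seed = 21))
  sub <- applyFilters(ds$sites, ds$proteins)$kept
  hits <- screenVariants(ds$variants, sub, proteins = ds$proteins)
  # brute force over the full cartesian product
  classes <- c("pathogenic", "likely_pathogenic")
  expected <- 0L
  for (i in seq_len(nrow(ds$variants))) {
    for (j in seq_len(nrow(sub))) {
      if (ds$variants$accession[i] == sub$accession[j] &&
          ds$variants$classification[i] %in% classes &&
          motifRole(sub$position[j],
                    ds$variants$protein_position[i]) != "other")
        expected <- expected + 1L
    }
  }
  expect_identical(nrow(hits), expected)
  # permuting either input changes nothing
  hits2 <- screenVariants(ds$variants[rev(seq_len(nrow(ds$variants))), ],
                          sub[sample(nrow(sub)), ], proteins = ds$proteins)
  expect_identical(hits, hits2)
  # idempotence: re-screening the same inputs is identical
  expect_identical(hits, screenVariants(ds$variants, sub,
                                        proteins = ds$proteins))
})
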