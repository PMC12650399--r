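test_that("window extraction pads termini and preserves coordinates", {
  expect_identical(extractWindow("MKTSAEQRL", position = 4), "____MKTSAEQRL__")
  # position 1: seven leading pads, center is the first residue
  w1 <- extractWindow("MKTSAEQRL", position = 1)
  expect_identical(substr(w1, 1, 7), strrep("_", 7))
  expect_identical(substr(w1, 8, 8), "M")
  # interior position in a long sequence: no pads at all
  sq <- strrep("ACDEFGHIKLMNPQRS", 4)
  w <- extractWindow(sq, position = 8)
  expect_identical(nchar(w), 15L)
  expect_false(grepl("_", w, fixed = TRUE))
  expect_error(extractWindow("MKT", position = 9), "out of bounds")
})

test_that("windows are length-preserving and position-consistent", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(8:60, 1)
    sq <- paste(sample(AA20, L, TRUE), collapse = "")
    pos <- sample(L, 1)
    w <- extractWindow(sq, position = pos)
    expect_identical(nchar(w), 15L)
    expect_identical(substr(w, 8, 8), substr(sq, pos, pos))
    # stripping pads and re-locating the core recovers the coordinates
    core <- gsub("_", "", w, fixed = TRUE)
    expect_identical(core, substr(sq, max(1, pos - 7), min(L, pos + 7)))
    nLead <- nchar(sub("^(_*).*$", "\\1", w))
    expect_identical(nLead, max(0L, 8L - pos))  # recovers the original offset
  }
})

test_that("motifRole classifies S-center, +2 and other positions", {
  expect_identical(motifRole(72, 74), "E_plus2")
  expect_identical(motifRole(72, 72), "S_center")
  expect_identical(motifRole(72, 73), "other")
  expect_identical(motifRole(72, 70), "other")
})

test_that("FASTA + TSV protein reading constructs entries and checks bounds", {
  dir <- withr::local_tempdir()
  writeLines(c(">P1 some description", "MKTSAEQRL"),
             file.path(dir, "p.fasta"))
  writeLines(c("accession\tgene\tcompartments\tsecretion_route",
               "P1\tG1\textracellular region\tclassical",
               "PX\tGX\tcytosol\tnone"),
             file.path(dir, "p.tsv"))
  expect_warning(
    ps <- readProteins(file.path(dir, "p.fasta"), file.path(dir, "p.tsv")),
    "absent accessions")
  expect_identical(accessions(ps), "P1")
  expect_identical(unname(Biostrings::width(sequences(ps))), 9L)
  expect_identical(compartments(ps)$P1, "extracellular region")
  # topology out of sequence bounds is a validity error naming the accession
  writeLines(c("accession\tstart\tend\tside",
               "P1\t20\t30\tcytoplasmic"), file.path(dir, "t.tsv"))
  suppressWarnings(
    expect_error(readProteins(file.path(dir, "p.fasta"),
                              file.path(dir, "p.tsv"),
                              file.path(dir, "t.tsv")),
                 "out of bounds.*P1"))
})

test_that("protein and phosphosite tables round-trip through disk", {
  dir <- withr::local_tempdir()
  ps <- toyProteins()
  paths <- file.path(dir, c("p.fasta", "a.tsv", "t.tsv"))
  writeProteins(ps, paths[1], paths[2], paths[3])
  ps2 <- readProteins(paths[1], paths[2], paths[3])
  expect_identical(as.character(sequences(ps2)), as.character(sequences(ps)))
  expect_identical(ps2@anno, ps@anno)
  expect_identical(ps2@topology[order(ps2@topology$accession,
                                      ps2@topology$start), ],
                   ps@topology)

  sites <- data.frame(accession = c("P1", "P2"), position = c(4L, 5L),
                      residue = "S", evidence = "large_scale",
                      source_compartment_terms = "",
                      stringsAsFactors = FALSE)
  f <- file.path(dir, "sites.tsv")
  writePhosphosites(sites, f)
  expect_identical(readPhosphosites(f)$position, c(4L, 5L))
  expect_identical(readPhosphosites(f)$accession, c("P1", "P2"))
})

test_that("site validation drops mismatches instead of correcting them", {
  ps <- toyProteins()
  sites <- data.frame(
    accession = c("P1", "P1", "ZZ", "P1"),
    position = c(4L, 5L, 3L, 99L),
    residue = c("S", "S", "S", "S"),  # position 5 of P1 is A, not S
    evidence = "large_scale", source_compartment_terms = "",
    stringsAsFactors = FALSE)
  expect_message(ok <- validateSites(sites, ps), "dropping 3")
  expect_identical(nrow(ok), 1L)
  expect_identical(ok$position, 4L)
  dropped <- attr(ok, "dropped")
  expect_setequal(dropped$reason,
                  c("residue_mismatch", "unmapped", "position_out_of_bounds"))
})

test_that("ProteinSet validity rejects overlapping or out-of-range topology", {
  expect_error(newProteinSet(
    c(P1 = "MKTSAEQRL"),
    topology = data.frame(accession = "P1", start = 2L, end = 20L,
                          side = "cytoplasmic")),
    "out of bounds")
  expect_error(newProteinSet(
    c(P1 = "MKTSAEQRLMKTSAEQRL"),
    topology = data.frame(accession = "P1", start = c(1L, 4L),
                          end = c(6L, 9L),
                          side = c("cytoplasmic", "transmembrane"))),
    "overlapping")
})

test_that("HGVS protein notation parses in both letter forms", {
  p <- parseHgvsP(c("p.Ser72Pro", "p.E74A", "S47C"))
  expect_identical(p$ref_aa, c("S", "E", "S"))
  expect_identical(p$protein_position, c(72L, 74L, 47L))
  expect_identical(p$alt_aa, c("P", "A", "C"))
  expect_identical(formatHgvsP("S", 72, "P"), "p.Ser72Pro")
  expect_error(parseHgvsP("p.Xyz12Ala"), "unknown residue")
  expect_error(parseHgvsP("nonsense"), "cannot parse")
})
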