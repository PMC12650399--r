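#' Synthetic stand-in for the curated substratome supplementary tables
#'
#' The published substratome tables (the curated phosphosite list and the
#' validated direct / knockout-responsive substrate lists) derive from a
#' licensed database export and are not redistributable. This builder
#' generates a deterministic SYNTHETIC dataset with the same composition:
#' 256 secretory-pathway proteins carrying 443 luminal S-x-E phosphosites
#' that all survive the filter cascade, of which 101 sites on 78 proteins
#' are marked as previously validated; plus decoy proteins/sites that the
#' cascade rejects (Thr centers, missing +2 glutamate, cytosolic
#' compartments, cytoplasmic-segment sites on membrane proteins,
#' non-classical secretion). Running [applyFilters()] and
#' [compareToValidated()] on it therefore recomputes the headline counts —
#' 443 sites / 256 proteins, 342 novel sites (77.2%), 178 novel proteins
#' (69.5%) — from scratch rather than reading them from anywhere. The real
#' supplementary tables, when available as TSV, can be loaded with
#' [readPhosphosites()] and compared identically.
#'
#' Composition is exact by construction: 187 proteins carry 2 sites and 69
#' carry 1 (443 total); 23 two-site proteins are fully validated (46 sites)
#' and 55 one-site proteins are validated (55 sites), giving 101 validated
#' sites on 78 proteins.
#'
#' @param seed Seed controlling sequences, accession assignment and decoys.
#' @return A list: `proteins` ([ProteinSet-class]), `sites` (phosphosite
#'   `data.frame`), `validatedSites` (`data.frame` accession/position),
#'   `validatedProteins` (character), `validatedWindows` (15-mers of the
#'   validated sites).
#' @export
syntheticSubstratomeFixture <- function(seed = 1L) {
  set.seed(stageSeed(seed, 11L))
  bg <- swissprotFrequencies()
  nKept <- 256L
  whitelist <- c("extracellular region", "endoplasmic reticulum lumen",
                 "Golgi lumen", "extracellular matrix",
                 "extracellular space")

  # two-site proteins first (187), then one-site proteins (69)
  nSites <- c(rep(2L, 187L), rep(1L, 69L))
  lens <- as.integer(round(stats::runif(nKept, 150, 600)))
  acc <- sprintf("SUBP%04d", seq_len(nKept))
  gene <- sprintf("SUBG%04d", seq_len(nKept))
  comp <- sample(whitelist, nKept, TRUE,
                 prob = c(0.45, 0.2, 0.1, 0.15, 0.1))
  seqList <- lapply(lens, function(L) sample(AA20, L, TRUE, bg))

  siteRows <- list()
  for (i in seq_len(nKept)) {
    pos <- sort(sample(seq(10L, lens[i] - 10L, by = 4L), nSites[i]))
    for (p in pos) {
      seqList[[i]][p] <- "S"
      seqList[[i]][p + 2L] <- "E"
    }
    siteRows[[i]] <- data.frame(accession = acc[i], position = pos,
                                stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, siteRows)
  sites$residue <- "S"

  # validated: 23 two-site proteins (both sites) + 55 one-site proteins
  vTwo <- sample(1:187, 23L)
  vOne <- sample(188:256, 55L)
  validatedProteins <- acc[sort(c(vTwo, vOne))]
  validatedSites <- sites[sites$accession %in% validatedProteins,
                          c("accession", "position"), drop = FALSE]
  vkey <- paste(sites$accession, sites$position)
  isVal <- vkey %in% paste(validatedSites$accession, validatedSites$position)
  sites$evidence <- ifelse(isVal,
                           sample(c("validated_direct", "ko_responsive"),
                                  nrow(sites), TRUE, prob = c(0.6, 0.4)),
                           "large_scale")
  sites$source_compartment_terms <- comp[match(sites$accession, acc)]

  # decoy proteins: one rejection reason each, ~12 per reason
  mkDecoy <- function(k, tag) {
    L <- as.integer(round(stats::runif(k, 120, 300)))
    list(acc = sprintf("DEC%s%03d", tag, seq_len(k)), len = L,
         seqs = lapply(L, function(x) sample(AA20, x, TRUE, bg)))
  }
  dThr <- mkDecoy(12L, "T"); dMot <- mkDecoy(12L, "M")
  dCyt <- mkDecoy(12L, "C"); dTop <- mkDecoy(12L, "P")
  dSec <- mkDecoy(12L, "N")
  decoySites <- list(); decoyAnno <- list(); decoyTopo <- list()
  addDecoy <- function(d, compTerm, routeD, center, plus2, topoSide) {
    for (j in seq_along(d$acc)) {
      p <- as.integer(floor(d$len[j] / 2L))
      d$seqs[[j]][p] <- center
      if (!is.null(plus2)) d$seqs[[j]][p + 2L] <- plus2
      decoySites[[length(decoySites) + 1L]] <<- data.frame(
        accession = d$acc[j], position = p, residue = center,
        evidence = "large_scale", source_compartment_terms = compTerm,
        stringsAsFactors = FALSE)
      decoyAnno[[length(decoyAnno) + 1L]] <<- data.frame(
        accession = d$acc[j], gene = paste0(d$acc[j], "G"),
        compartments = compTerm, secretion_route = routeD,
        stringsAsFactors = FALSE)
      if (!is.null(topoSide)) {
        # site sits in the C-terminal segment with the requested side
        decoyTopo[[length(decoyTopo) + 1L]] <<- data.frame(
          accession = d$acc[j],
          start = c(1L, p - 25L, p - 5L),
          end = c(p - 26L, p - 6L, d$len[j]),
          side = c("luminal_or_extracellular", "transmembrane", topoSide),
          stringsAsFactors = FALSE)
      }
    }
    d
  }
  dThr <- addDecoy(dThr, "extracellular region", "classical", "T", "E", NULL)
  dMot <- addDecoy(dMot, "extracellular region", "classical", "S", "A", NULL)
  dCyt <- addDecoy(dCyt, "cytosol", "none", "S", "E", NULL)
  dTop <- addDecoy(dTop, "extracellular region", "classical", "S", "E",
                   "cytoplasmic")
  dSec <- addDecoy(dSec, "extracellular region", "non_classical", "S", "E",
                   NULL)

  allAcc <- c(acc, dThr$acc, dMot$acc, dCyt$acc, dTop$acc, dSec$acc)
  allSeq <- c(seqList, dThr$seqs, dMot$seqs, dCyt$seqs, dTop$seqs, dSec$seqs)
  anno <- rbind(
    data.frame(accession = acc, gene = gene, compartments = comp,
               secretion_route = "classical", stringsAsFactors = FALSE),
    do.call(rbind, decoyAnno))
  topo <- if (length(decoyTopo)) do.call(rbind, decoyTopo)
  else data.frame(accession = character(0), start = integer(0),
                  end = integer(0), side = character(0))
  proteins <- newProteinSet(
    setNames(vapply(allSeq, paste, character(1), collapse = ""), allAcc),
    anno, topo)
  sites <- rbind(sites[, c("accession", "position", "residue", "evidence",
                           "source_compartment_terms")],
                 do.call(rbind, decoySites))
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  rownames(sites) <- NULL

  seqs <- as.character(proteins@sequences)
  validatedWindows <- vapply(seq_len(nrow(validatedSites)), function(i) {
    extractWindow(seqs[[validatedSites$accession[i]]],
                  position = validatedSites$position[i])
  }, character(1))
  list(proteins = proteins, sites = sites,
       validatedSites = validatedSites,
       validatedProteins = validatedProteins,
       validatedWindows = validatedWindows)
}

#' Synthetic stand-in for the validated direct-substrate window table
#'
#' The published table of validated direct-substrate phosphosite windows is
#' not redistributable; this builder emulates its composition: `n` 15-mer
#' windows with Swiss-Prot background residues, a serine-dominated center,
#' and glutamate at +2 in `round(eFraction * n)` windows (the +2 residue of
#' the remainder is drawn from the non-E background). The default plants
#' E@+2 in 78% of windows, the conservation level reported for validated
#' substrates.
#'
#' @param seed Seed.
#' @param n Number of windows, default 130.
#' @param eFraction Fraction of windows with glutamate at +2, default 0.78.
#' @param serCenterFraction Fraction of serine (vs threonine) centers.
#' @return Character vector of `n` windows.
#' @export
syntheticValidatedWindows <- function(seed = 1L, n = 130L, eFraction = 0.78,
                                      serCenterFraction = 0.9) {
  set.seed(stageSeed(seed, 12L))
  bg <- swissprotFrequencies()
  w <- sampleBackgroundRaw(n, bg)
  center <- ifelse(stats::runif(n) < serCenterFraction, "S", "T")
  nE <- as.integer(round(eFraction * n))
  hasE <- sample(c(rep(TRUE, nE), rep(FALSE, n - nE)))
  plus2 <- ifelse(hasE, "E", drawResidue(n, bg, exclude = "E"))
  substr(w, 8L, 8L) <- center
  substr(w, 10L, 10L) <- plus2
  w
}

#' Synthetic acidophilic-kinase peptide-library panel
#'
#' A 32-kinase panel of position-specific scoring matrices over offsets
#' −5..+4, emulating a peptide-library specificity screen of acidophilic
#' kinases: one planted +2-glutamate specialist (named `FAM20C`), a block of
#' kinases with glutamate preference at positions other than +2 (CK2-like
#' +1/+3 acidophiles), a block preferring aspartate, and unbiased kinases.
#' Only the specialist has glutamate as the dominant residue at +2.
#'
#' @param seed Seed (controls which kinases carry which decoy pattern).
#' @param nKinases Panel size, default 32.
#' @return Named list of [KinasePSSM-class].
#' @export
syntheticKinasePanel <- function(seed = 1L, nKinases = 32L) {
  set.seed(stageSeed(seed, 13L))
  offs <- as.character(-5:4)
  base <- function() matrix(1, 20L, length(offs), dimnames = list(AA20, offs))
  pssms <- vector("list", nKinases)
  patterns <- sample(rep(c("ck2_like", "asp_like", "uniform"),
                         length.out = nKinases - 1L))
  for (i in seq_len(nKinases - 1L)) {
    m <- base()
    if (patterns[i] == "ck2_like") m["E", c("1", "3")] <- 8
    if (patterns[i] == "asp_like") m["D", c("1", "2")] <- 8
    pssms[[i]] <- newKinasePSSM(sprintf("KIN%02d", i), m)
  }
  m <- base()
  m["E", "2"] <- 8  # the planted +2 specialist
  pssms[[nKinases]] <- newKinasePSSM("FAM20C", m)
  names(pssms) <- vapply(pssms, function(p) p@kinase, character(1))
  pssms[sample(names(pssms))]
}

#' Synthetic clinical-variant fixture for the motif screen
#'
#' Four secretory proteins with SYNTHETIC sequences (real canonical
#' sequences are not redistributed with the package) carrying luminal S-x-E
#' phosphosites at the positions of published clinical interest:
#' a transthyretin-like protein (gene `TTR`, site Ser72/Glu74), a
#' PCSK9-like protein (Ser47), a von Willebrand factor-like protein
#' (Ser1517), and one additional protein carrying only a variant of
#' uncertain significance. Variants mirror the reported ClinVar records:
#' `TTR` p.Ser72Pro (pathogenic), p.Glu74Ala (pathogenic), p.Glu74Gly
#' (likely pathogenic), p.Glu74Lys and p.Glu74Gln (pathogenic/likely
#' pathogenic with a conflicting uncertain submission each), `PCSK9`
#' p.Ser47Cys (pathogenic), `VWF` p.Ser1517Arg (likely pathogenic).
#'
#' @param seed Seed for the synthetic sequence backbone.
#' @return A list: `proteins` ([ProteinSet-class]), `sites` (phosphosite
#'   `data.frame`), `variants` (variant `data.frame`).
#' @export
syntheticVariantFixture <- function(seed = 1L) {
  set.seed(stageSeed(seed, 14L))
  bg <- swissprotFrequencies()
  spec <- data.frame(
    gene = c("TTR", "PCSK9", "VWF", "SYNX1"),
    accession = c("TTR_SYN", "PCSK9_SYN", "VWF_SYN", "SYNX1_SYN"),
    length = c(147L, 692L, 2813L, 120L),
    site = c(72L, 47L, 1517L, 60L),
    stringsAsFactors = FALSE)
  seqs <- vapply(seq_len(nrow(spec)), function(i) {
    s <- sample(AA20, spec$length[i], TRUE, bg)
    s[spec$site[i]] <- "S"
    s[spec$site[i] + 2L] <- "E"
    paste(s, collapse = "")
  }, character(1))
  proteins <- newProteinSet(
    setNames(seqs, spec$accession),
    data.frame(accession = spec$accession, gene = spec$gene,
               compartments = "extracellular region",
               secretion_route = "classical", stringsAsFactors = FALSE))
  sites <- data.frame(accession = spec$accession, position = spec$site,
                      residue = "S", evidence = "large_scale",
                      source_compartment_terms = "extracellular region",
                      stringsAsFactors = FALSE)
  v <- function(gene, hgvs, cls, cond) {
    data.frame(gene = gene,
               accession = spec$accession[match(gene, spec$gene)],
               hgvs_p = hgvs, classification = cls, condition = cond,
               stringsAsFactors = FALSE)
  }
  amyl <- "Amyloidosis, hereditary systemic 1"
  variants <- rbind(
    v("TTR", "p.Ser72Pro", "pathogenic", amyl),
    v("TTR", "p.Glu74Ala", "pathogenic", amyl),
    v("TTR", "p.Glu74Gly", "likely_pathogenic", amyl),
    v("TTR", "p.Glu74Lys", "pathogenic", amyl),
    v("TTR", "p.Glu74Lys", "uncertain", amyl),
    v("TTR", "p.Glu74Gln", "likely_pathogenic", amyl),
    v("TTR", "p.Glu74Gln", "uncertain", amyl),
    v("PCSK9", "p.Ser47Cys", "pathogenic", "Familial hypercholesterolemia"),
    v("VWF", "p.Ser1517Arg", "likely_pathogenic",
      "von Willebrand disease type 2"),
    v("SYNX1", "p.Ser60Ala", "uncertain", "simulated condition"))
  variants <- cbind(variants, parseHgvsP(variants$hgvs_p))
  list(proteins = proteins, sites = sites, variants = variants)
}

#' Synthetic annotation gene-set collection with one planted program
#'
#' Builds a gene-set collection over a gene universe: random annotation
#' terms of varying size, plus one planted term (default
#' `"coagulation_like"`) composed mostly of a supplied gene selection —
#' used to verify that over-representation analysis recovers a planted
#' functional program.
#'
#' @param universe Character vector of all gene identifiers.
#' @param planted Character vector of genes forming the planted program
#'   (a subset of `universe`), or `NULL` for a purely random collection.
#' @param nSets Number of random terms, default 20.
#' @param seed Seed.
#' @return A collection as returned by [geneSetCollection()].
#' @export
syntheticGeneSets <- function(universe, planted = NULL, nSets = 20L,
                              seed = 1L) {
  set.seed(stageSeed(seed, 15L))
  sets <- lapply(seq_len(nSets), function(i) {
    sample(universe, max(5L, min(length(universe),
                                 as.integer(round(stats::runif(1, 5, 40))))))
  })
  names(sets) <- sprintf("random_term_%02d", seq_len(nSets))
  if (!is.null(planted) && length(planted)) {
    core <- sample(planted, min(length(planted), 25L))
    pad <- sample(setdiff(universe, core), min(5L, length(universe) - length(core)))
    sets[["coagulation_like"]] <- c(core, pad)
  }
  geneSetCollection(sets, name = "synthetic_annotation", universe = universe)
}
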