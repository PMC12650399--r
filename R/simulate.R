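#' Configuration of the synthetic phosphoproteome generator
#'
#' Defaults describe the study conditions the rest of the package is tested
#' under: a few hundred proteins mixing secretory, cytosolic and nuclear
#' compartments; secretory serine phosphosites carrying a planted glutamate
#' at +2 in 80% of cases (the motif-dependence rate reported for the
#' secretome of knockout cell lines); strong serine preference at the
#' phosphoacceptor; Swiss-Prot average composition for all unplanted
#' residues; and a 10,000-window random-peptide background.
#'
#' @param nProteins Number of proteins.
#' @param meanProteinLength Mean protein length (aa, sd = mean/4, floor 30).
#' @param compartmentMix Named probabilities over compartment terms.
#' @param nSitesSecretory,nSitesCytosol,nSitesNuclear Phosphosite counts per
#'   compartment stratum.
#' @param fEplus2 Probability a secretory Ser site gets glutamate planted at
#'   +2 (otherwise the +2 residue is drawn from the non-E background, so the
#'   realized E fraction equals `fEplus2` in expectation).
#' @param serFraction Probability a site is Ser rather than Thr.
#' @param backgroundFreqs Residue composition for sequences and background
#'   windows (named over [AA20], sums to 1).
#' @param nBackgroundPeptides Number of background windows.
#' @param membraneFraction Probability a protein is membrane-anchored (gets
#'   luminal/transmembrane/cytoplasmic segments).
#' @param nonclassicalFraction Probability an extracellular protein is
#'   flagged as non-classically secreted.
#' @param cytosolicMotifs Plant Pro at +1 and Arg at −3 enrichment in the
#'   cytosolic stratum (proline-directed / basophilic kinase signature),
#'   default FALSE.
#' @param nVariants Number of simulated missense variants.
#' @param variantMotifHitFraction Probability a planted variant lands on a
#'   motif S-center or +2 position (classified pathogenic/likely pathogenic);
#'   others land off-motif with mixed classifications.
#' @param seed Global seed; each generator stage derives its own stream from
#'   it by fixed offsets, so stages are independently reproducible.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nProteins = 260L,
                             meanProteinLength = 400L,
                             compartmentMix = c("extracellular region" = 0.22,
                                                "endoplasmic reticulum lumen" = 0.13,
                                                "Golgi lumen" = 0.10,
                                                "cytosol" = 0.33,
                                                "nuclear matrix" = 0.22),
                             nSitesSecretory = 500L,
                             nSitesCytosol = 300L,
                             nSitesNuclear = 200L,
                             fEplus2 = 0.8,
                             serFraction = 0.85,
                             backgroundFreqs = swissprotFrequencies(),
                             nBackgroundPeptides = 10000L,
                             membraneFraction = 0.25,
                             nonclassicalFraction = 0.1,
                             cytosolicMotifs = FALSE,
                             nVariants = 60L,
                             variantMotifHitFraction = 0.5,
                             seed = 1L) {
  new("SimulationConfig",
      nProteins = as.integer(nProteins),
      meanProteinLength = as.integer(meanProteinLength),
      compartmentMix = compartmentMix / sum(compartmentMix),
      nSitesSecretory = as.integer(nSitesSecretory),
      nSitesCytosol = as.integer(nSitesCytosol),
      nSitesNuclear = as.integer(nSitesNuclear),
      fEplus2 = fEplus2, serFraction = serFraction,
      backgroundFreqs = backgroundFreqs / sum(backgroundFreqs),
      nBackgroundPeptides = as.integer(nBackgroundPeptides),
      membraneFraction = membraneFraction,
      nonclassicalFraction = nonclassicalFraction,
      cytosolicMotifs = cytosolicMotifs,
      nVariants = as.integer(nVariants),
      variantMotifHitFraction = variantMotifHitFraction,
      seed = as.integer(seed))
}

# Fixed stream splitting: each stage draws from its own seed derived from the
# global one, so regenerating one stage never perturbs another.
stageSeed <- function(seed, stage) (as.integer(seed) %% 1000003L) * 1000L + stage

SECRETORY_TERMS <- c("golgi lumen", "endoplasmic reticulum lumen",
                     "extracellular matrix", "extracellular region",
                     "extracellular space")

# Draw one residue from freqs, optionally excluding some letters.
drawResidue <- function(n, freqs, exclude = NULL) {
  if (!is.null(exclude)) {
    freqs <- freqs[setdiff(names(freqs), exclude)]
    freqs <- freqs / sum(freqs)
  }
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Simulate a full synthetic dataset
#'
#' Generates proteins (sequences, compartments, topology, secretion route),
#' phosphosites with planted motif structure, background windows, and
#' missense variants. Deterministic given `config@seed`. Site positions are
#' placed on a 3-residue grid within `[4, length - 3]` of each protein so
#' planted center/+2 residues never collide. Membrane proteins receive a
#' luminal / transmembrane / cytoplasmic segment triple; 15% of secretory
#' sites on membrane proteins are deliberately placed in the cytoplasmic
#' segment to emulate the annotation noise the filter cascade removes.
#' A small fraction of secretory motif sites carries `validated_direct` or
#' `ko_responsive` evidence so the novelty comparison is exercised end to
#' end.
#'
#' @param config A [SimulationConfig-class].
#' @return A list: `proteins` ([ProteinSet-class]), `sites` (phosphosite
#'   `data.frame` with an added `stratum` column), `background` (character
#'   windows), `variants` (variant `data.frame`), and `truth` (generator
#'   bookkeeping: per-stratum site counts and the planted E@+2 indicator for
#'   secretory Ser sites).
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  bg <- config@backgroundFreqs

  ## stage 1: proteins -------------------------------------------------
  set.seed(stageSeed(config@seed, 1L))
  n <- config@nProteins
  lens <- pmax(30L, as.integer(round(
    stats::rnorm(n, config@meanProteinLength, config@meanProteinLength / 4))))
  acc <- sprintf("SYNP%04d", seq_len(n))
  gene <- sprintf("SYNG%04d", seq_len(n))
  seqList <- lapply(lens, function(L) sample(AA20, L, TRUE, bg))
  comp <- sample(names(config@compartmentMix), n, TRUE,
                 config@compartmentMix)
  isSec <- tolower(comp) %in% SECRETORY_TERMS
  isCyt <- tolower(comp) == "cytosol"
  isNuc <- !isSec & !isCyt
  route <- ifelse(isSec, "classical", "none")
  isExtra <- tolower(comp) %in% c("extracellular matrix",
                                  "extracellular region",
                                  "extracellular space")
  route[isExtra & stats::runif(n) < config@nonclassicalFraction] <-
    "non_classical"
  isMem <- stats::runif(n) < config@membraneFraction & lens >= 90L
  topo <- do.call(rbind, lapply(which(isMem), function(i) {
    L <- lens[i]
    a <- as.integer(floor(L * 0.6))  # luminal N-terminal part
    data.frame(accession = acc[i],
               start = c(1L, a, a + 20L),
               end = c(a - 1L, a + 19L, L),
               side = c("luminal_or_extracellular", "transmembrane",
                        "cytoplasmic"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(topo))
    topo <- data.frame(accession = character(0), start = integer(0),
                       end = integer(0), side = character(0),
                       stringsAsFactors = FALSE)

  ## stage 2: phosphosites ---------------------------------------------
  set.seed(stageSeed(config@seed, 2L))
  # candidate grid positions per protein; spacing 10 keeps each site's
  # planted center/+2 residues outside every other site's -7..+7 window,
  # so flanking-column statistics of different sites stay independent
  gridPos <- function(i, luminalOnly = FALSE, cytoOnly = FALSE) {
    L <- lens[i]
    pos <- seq(8L, L - 3L, by = 10L)
    if (isMem[i]) {
      a <- as.integer(floor(L * 0.6))
      if (luminalOnly) pos <- pos[pos <= a - 3L]
      if (cytoOnly) pos <- pos[pos >= a + 23L]
    }
    pos
  }
  placeSites <- function(idx, nSites, stratum) {
    if (nSites == 0L)
      return(data.frame(protein = integer(0), position = integer(0),
                        stratum = character(0)))
    if (length(idx) == 0L)
      stop("no proteins available for stratum ", stratum)
    slots <- do.call(rbind, lapply(idx, function(i) {
      lum <- !isMem[i] || stats::runif(1) > 0.15
      pos <- gridPos(i, luminalOnly = isMem[i] && lum,
                     cytoOnly = isMem[i] && !lum)
      if (length(pos) == 0L) return(NULL)
      data.frame(protein = i, position = pos)
    }))
    if (is.null(slots) || nrow(slots) < nSites)
      stop("infeasible config: ", nSites, " sites requested for stratum ",
           stratum, " but only ", if (is.null(slots)) 0L else nrow(slots),
           " candidate positions exist")
    pick <- slots[sample.int(nrow(slots), nSites), , drop = FALSE]
    pick$stratum <- stratum
    pick
  }
  sitesTab <- rbind(
    placeSites(which(isSec), config@nSitesSecretory, "secretory"),
    placeSites(which(isCyt), config@nSitesCytosol, "cytosol"),
    placeSites(which(isNuc), config@nSitesNuclear, "nuclear"))
  m <- nrow(sitesTab)
  residue <- ifelse(stats::runif(m) < config@serFraction, "S", "T")
  plantedE <- logical(m)
  for (r in seq_len(m)) {
    i <- sitesTab$protein[r]; p <- sitesTab$position[r]
    seqList[[i]][p] <- residue[r]
    if (sitesTab$stratum[r] == "secretory" && residue[r] == "S") {
      if (stats::runif(1) < config@fEplus2) {
        seqList[[i]][p + 2L] <- "E"
        plantedE[r] <- TRUE
      } else {
        seqList[[i]][p + 2L] <- drawResidue(1L, bg, exclude = "E")
      }
    }
    if (config@cytosolicMotifs && sitesTab$stratum[r] == "cytosol") {
      if (stats::runif(1) < 0.4) seqList[[i]][p + 1L] <- "P"
      if (stats::runif(1) < 0.25 && p > 3L) seqList[[i]][p - 3L] <- "R"
    }
  }
  evidence <- rep("large_scale", m)
  motifIdx <- which(sitesTab$stratum == "secretory" & residue == "S" &
                      plantedE)
  if (length(motifIdx) >= 10L) {
    nv <- max(1L, as.integer(round(0.08 * length(motifIdx))))
    pickV <- sample(motifIdx, min(2L * nv, length(motifIdx)))
    evidence[pickV[seq_len(nv)]] <- "validated_direct"
    evidence[pickV[-seq_len(nv)]] <- "ko_responsive"
  }
  sites <- data.frame(accession = acc[sitesTab$protein],
                      position = sitesTab$position,
                      residue = residue,
                      evidence = evidence,
                      source_compartment_terms = comp[sitesTab$protein],
                      stratum = sitesTab$stratum,
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  rownames(sites) <- NULL

  seqs <- setNames(vapply(seqList, paste, character(1), collapse = ""), acc)
  proteins <- newProteinSet(
    seqs,
    data.frame(accession = acc, gene = gene, compartments = comp,
               secretion_route = route, stringsAsFactors = FALSE),
    topo)

  ## stage 3: background windows ---------------------------------------
  set.seed(stageSeed(config@seed, 3L))
  background <- sampleBackgroundRaw(config@nBackgroundPeptides, bg)

  ## stage 4: variants --------------------------------------------------
  set.seed(stageSeed(config@seed, 4L))
  variants <- simulateVariants(config, proteins, sites)

  truth <- list(
    n_sites = m,
    stratum_counts = table(sites$stratum),
    secretory_ser = sites$stratum == "secretory" & sites$residue == "S",
    planted_E_plus2 = {
      plus2 <- substr(seqs[sites$accession], sites$position + 2L,
                      sites$position + 2L)
      sites$stratum == "secretory" & sites$residue == "S" & plus2 == "E"
    })
  list(proteins = proteins, sites = sites, background = background,
       variants = variants, truth = truth, config = config)
}

# Internal: n iid windows of length 2*radius+1 from residue frequencies.
sampleBackgroundRaw <- function(n, freqs, radius = 7L) {
  wlen <- 2L * radius + 1L
  ch <- sample(names(freqs), n * wlen, TRUE, freqs)
  vapply(seq_len(n),
         function(i) paste(ch[((i - 1L) * wlen + 1L):(i * wlen)],
                           collapse = ""),
         character(1))
}

#' Sample random background peptides
#'
#' Windows of length `2 * radius + 1` drawn i.i.d. from the configured
#' residue composition — the random-peptide background the probability-logo
#' statistic is computed against. No pad characters.
#'
#' @param config A [SimulationConfig-class] (uses `backgroundFreqs`,
#'   `nBackgroundPeptides`, and the background stream of `seed`).
#' @param radius Window radius, default 7.
#' @return Character vector of windows.
#' @export
sampleBackground <- function(config, radius = 7L) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@nBackgroundPeptides < 1L) stop("need at least one peptide")
  set.seed(stageSeed(config@seed, 3L))
  sampleBackgroundRaw(config@nBackgroundPeptides, config@backgroundFreqs,
                      radius)
}

# Internal: missense variants, a fraction planted on motif S/+2 positions.
simulateVariants <- function(config, proteins, sites) {
  nv <- config@nVariants
  empty <- data.frame(gene = character(0), accession = character(0),
                      hgvs_p = character(0), classification = character(0),
                      condition = character(0), ref_aa = character(0),
                      protein_position = integer(0), alt_aa = character(0),
                      stringsAsFactors = FALSE)
  if (nv == 0L) return(empty)
  seqs <- as.character(proteins@sequences)
  genes <- setNames(proteins@anno$gene, proteins@anno$accession)
  plus2 <- substr(seqs[sites$accession], sites$position + 2L,
                  sites$position + 2L)
  motif <- sites[sites$residue == "S" & plus2 == "E", , drop = FALSE]
  rows <- vector("list", nv)
  for (i in seq_len(nv)) {
    onMotif <- nrow(motif) > 0L &&
      stats::runif(1) < config@variantMotifHitFraction
    if (onMotif) {
      s <- motif[sample.int(nrow(motif), 1L), ]
      role <- sample(c("S_center", "E_plus2"), 1L)
      pos <- if (role == "S_center") s$position else s$position + 2L
      accI <- s$accession
      cls <- sample(c("pathogenic", "likely_pathogenic"), 1L)
      cond <- "simulated motif disorder"
    } else {
      accI <- sample(names(seqs), 1L)
      pos <- sample.int(nchar(seqs[[accI]]), 1L)
      # stay off any annotated site's center/+2
      near <- sites$accession == accI &
        (sites$position == pos | sites$position + 2L == pos)
      if (any(near)) pos <- max(1L, pos - 1L)
      cls <- sample(c("pathogenic", "likely_pathogenic", "uncertain",
                      "benign", "likely_benign"), 1L,
                    prob = c(0.1, 0.1, 0.4, 0.25, 0.15))
      cond <- "simulated background condition"
    }
    ref <- substr(seqs[[accI]], pos, pos)
    alt <- drawResidue(1L, setNames(rep(1 / 20, 20L), AA20), exclude = ref)
    rows[[i]] <- data.frame(gene = unname(genes[accI]), accession = accI,
                            hgvs_p = formatHgvsP(ref, pos, alt),
                            classification = cls, condition = cond,
                            ref_aa = ref, protein_position = pos,
                            alt_aa = alt, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("accession", "hgvs_p", "classification")]), ,
             drop = FALSE]
  out <- out[order(out$accession, out$protein_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' FASTA for sequences; TSV for annotations, topology, phosphosites,
#' background windows and variants — the same files [readProteins()],
#' [readPhosphosites()] and [readVariants()] read back.
#'
#' @param dataset The list returned by [simulateDataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             annotations = file.path(dir, "annotations.tsv"),
             topology = file.path(dir, "topology.tsv"),
             sites = file.path(dir, "phosphosites.tsv"),
             background = file.path(dir, "background_windows.tsv"),
             variants = file.path(dir, "variants.tsv"))
  writeProteins(dataset$proteins, paths["fasta"], paths["annotations"],
                paths["topology"])
  writePhosphosites(dataset$sites[, c("accession", "position", "residue",
                                      "evidence",
                                      "source_compartment_terms")],
                    paths["sites"])
  write.table(data.frame(window = dataset$background), paths["background"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeVariants(dataset$variants, paths["variants"])
  invisible(paths)
}
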