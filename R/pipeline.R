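#' Run the full analysis workflow on a synthetic dataset
#'
#' Orchestrates the stages end to end: simulate a dataset, write its input
#' files, apply the substratome filter cascade, run the stratified
#' probability-logo analysis (secretory Ser, secretory Thr, cytosolic Ser,
#' nuclear Ser) against the random-peptide background, compare the putative
#' substratome to the simulated validated lists, run annotation enrichment
#' on a synthetic gene-set collection with a planted program, and screen the
#' simulated variants against the substratome. All outputs are plain TSV /
#' JSON under `outDir`; a `manifest.json` records the inputs, configuration,
#' seed and package version. Deterministic: the same configuration and seed
#' reproduce byte-identical outputs.
#'
#' @param outDir Output directory (created; must be empty or absent).
#' @param config A [SimulationConfig-class], default [simulationConfig()].
#' @param filter A [FilterConfig-class], default [filterConfig()].
#' @param alpha Significance level for logo thresholds and enrichment.
#' @return Invisibly, a list of the in-memory stage results: `dataset`,
#'   `substratome`, `logos`, `novelty`, `summary`, `enrichment`, `hits`.
#' @export
runPipeline <- function(outDir, config = simulationConfig(),
                        filter = filterConfig(), alpha = 0.05) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ds <- simulateDataset(config)
  inputPaths <- writeDataset(ds, file.path(outDir, "inputs"))

  ## substratome
  sub <- applyFilters(ds$sites, ds$proteins, filter)
  writeSubstratome(sub, file.path(outDir, "substratome.tsv"),
                   file.path(outDir, "rejected.tsv"))
  summ <- summarizeSubstratome(sub$kept)

  ## stratified logos
  win <- extractWindows(ds$sites, ds$proteins)
  strata <- list(
    ser_secretory = win$window[win$stratum == "secretory" & win$residue == "S"],
    thr_secretory = win$window[win$stratum == "secretory" & win$residue == "T"],
    ser_cytosol = win$window[win$stratum == "cytosol" & win$residue == "S"],
    ser_nuclear = win$window[win$stratum == "nuclear" & win$residue == "S"])
  strata <- strata[lengths(strata) > 0L]
  logos <- stratifiedCompare(strata, ds$background, alpha = alpha)
  for (nm in names(logos))
    writeLogoMatrix(logos[[nm]], file.path(outDir, paste0("logo_", nm)))

  ## novelty comparison against the simulated validated lists
  validated <- ds$sites[ds$sites$evidence != "large_scale",
                        c("accession", "position"), drop = FALSE]
  novelty <- compareToValidated(sub$kept, validated)
  jsonlite::write_json(novelty, file.path(outDir, "novelty.json"),
                       auto_unbox = TRUE, digits = NA)

  ## enrichment with a planted program among substratome genes
  universe <- ds$proteins@anno$gene
  subGenes <- unique(sub$kept$gene)
  collection <- syntheticGeneSets(universe, planted = subGenes,
                                  seed = config@seed)
  enr <- enrich(subGenes, collection, alpha = alpha)
  write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## variant screen
  hits <- screenVariants(ds$variants, sub$kept, proteins = ds$proteins)
  writeHitReport(hits, file.path(outDir, "variant_hits.tsv"))

  manifest <- list(
    package = "substratomics",
    version = as.character(utils::packageVersion("substratomics")),
    seed = config@seed,
    alpha = alpha,
    inputs = as.list(setNames(basename(inputPaths), names(inputPaths))),
    simulation = list(n_proteins = config@nProteins,
                      n_sites = c(secretory = config@nSitesSecretory,
                                  cytosol = config@nSitesCytosol,
                                  nuclear = config@nSitesNuclear),
                      f_E_plus2 = config@fEplus2,
                      ser_fraction = config@serFraction),
    filter = list(whitelist = filter@compartmentWhitelist,
                  require_center = filter@requireCenter,
                  require_E_plus2 = filter@requireEplus2,
                  exclude_nonclassical = filter@excludeNonclassical,
                  enforce_topology = filter@enforceTopology),
    summary = list(n_sites = summ$n_sites, n_proteins = summ$n_proteins,
                   e_plus2_fraction = summ$e_plus2_fraction,
                   novelty = novelty))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = ds, substratome = sub, logos = logos,
                 novelty = novelty, summary = summ, enrichment = enr,
                 hits = hits))
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts a structured config with optional `simulation`, `filter` and
#' `alpha` blocks; unset fields keep package defaults. Field names match
#' the arguments of [simulationConfig()] and [filterConfig()].
#'
#' @param path YAML file path.
#' @return A list with elements `config` ([SimulationConfig-class]),
#'   `filter` ([FilterConfig-class]) and `alpha`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulationConfig, as.list(y$simulation %||% list()))
  flt <- do.call(filterConfig, as.list(y$filter %||% list()))
  list(config = sim, filter = flt, alpha = y$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
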