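#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' ProteinSet: sequences plus secretory-pathway annotations
#'
#' Container pairing an [Biostrings::AAStringSet] of protein sequences
#' (named by accession) with the annotations the substratome filter cascade
#' consumes: compartment terms, membrane-topology segments, and secretion
#' route.
#'
#' @slot sequences An `AAStringSet`, one entry per accession.
#' @slot anno A `data.frame` with columns `accession`, `gene`,
#'   `compartments` (semicolon-separated controlled-vocabulary terms, possibly
#'   empty) and `secretion_route` (`"classical"`, `"non_classical"` or
#'   `"none"`).
#' @slot topology A `data.frame` with columns `accession`, `start`, `end`
#'   (1-based inclusive) and `side` (`"luminal_or_extracellular"`,
#'   `"cytoplasmic"` or `"transmembrane"`). May have zero rows (all proteins
#'   soluble).
#'
#' Validity requires non-empty sequences over the 20-letter alphabet,
#' one annotation row per sequence, and topology segments that are
#' non-overlapping within each accession and inside `[1, length(sequence)]`.
#'
#' @seealso [readProteins()], [extractWindow()], [applyFilters()]
#' @export
setClass("ProteinSet",
  representation(sequences = "AAStringSet",
                 anno = "data.frame",
                 topology = "data.frame"))

setValidity("ProteinSet", function(object) {
  msgs <- character(0)
  seqs <- object@sequences
  if (length(seqs) == 0L) msgs <- c(msgs, "no sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    msgs <- c(msgs, "sequences must be uniquely named by accession")
  chars <- unique(unlist(strsplit(as.character(seqs), "", fixed = TRUE)))
  bad <- setdiff(chars, AA20)
  if (length(bad))
    msgs <- c(msgs, paste0("sequence characters outside 20-letter alphabet: ",
                           paste(bad, collapse = ",")))
  need <- c("accession", "gene", "compartments", "secretion_route")
  if (!all(need %in% names(object@anno)))
    msgs <- c(msgs, paste0("anno must have columns ",
                           paste(need, collapse = ", ")))
  else {
    if (!setequal(object@anno$accession, names(seqs)) ||
        anyDuplicated(object@anno$accession))
      msgs <- c(msgs, "anno must have exactly one row per sequence accession")
    badRoute <- setdiff(object@anno$secretion_route,
                        c("classical", "non_classical", "none"))
    if (length(badRoute))
      msgs <- c(msgs, paste0("unknown secretion_route: ",
                             paste(badRoute, collapse = ",")))
  }
  topo <- object@topology
  needT <- c("accession", "start", "end", "side")
  if (!all(needT %in% names(topo)))
    msgs <- c(msgs, "topology must have columns accession, start, end, side")
  else if (nrow(topo)) {
    badSide <- setdiff(topo$side,
                       c("luminal_or_extracellular", "cytoplasmic",
                         "transmembrane"))
    if (length(badSide))
      msgs <- c(msgs, paste0("unknown topology side: ",
                             paste(badSide, collapse = ",")))
    lens <- setNames(Biostrings::width(seqs), names(seqs))
    for (acc in unique(topo$accession)) {
      if (!acc %in% names(lens)) {
        msgs <- c(msgs, paste0("topology references unknown accession ", acc))
        next
      }
      seg <- topo[topo$accession == acc, , drop = FALSE]
      if (any(seg$start < 1L) || any(seg$end > lens[[acc]]) ||
          any(seg$start > seg$end))
        msgs <- c(msgs,
                  paste0("topology segment out of bounds for accession ", acc))
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)]))
        msgs <- c(msgs, paste0("overlapping topology segments for accession ",
                               acc))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LogoMatrix: position-specific residue counts, frequencies and significance
#'
#' Result of probability-logo analysis of a set of equal-length sequence
#' windows. Rows are the 20 residues, columns are signed offsets around the
#' phosphosite (−7..+7 for the default radius). Pad characters are excluded
#' from column totals; the center column (offset 0) is carried descriptively
#' but excluded from significance testing.
#'
#' @slot nWindows Number of windows counted.
#' @slot counts Integer matrix residue x offset.
#' @slot freqs Numeric matrix, `counts` divided by its column totals (`NaN`
#'   where a column has total 0, e.g. all-pad).
#' @slot heights Numeric matrix of signed log10 binomial-tail significances
#'   (positive = over-represented relative to background), or a 0x0 matrix
#'   before [logoHeights()] is applied.
#' @slot background Named numeric background residue frequencies (sum 1).
#' @slot bonferroni Bonferroni threshold on the −log10 scale (`NA_real_`
#'   before heights are computed).
#' @slot centerComposition Named integer counts of the center residue
#'   (S vs T composition of the window set).
#' @export
setClass("LogoMatrix",
  representation(nWindows = "integer",
                 counts = "matrix",
                 freqs = "matrix",
                 heights = "matrix",
                 background = "numeric",
                 bonferroni = "numeric",
                 centerComposition = "integer"))

setValidity("LogoMatrix", function(object) {
  msgs <- character(0)
  if (!identical(rownames(object@counts), AA20))
    msgs <- c(msgs, "counts rows must be the 20-residue alphabet")
  if (any(object@counts < 0L))
    msgs <- c(msgs, "negative counts")
  tot <- colSums(object@counts)
  ok <- tot > 0
  if (any(abs(colSums(object@freqs[, ok, drop = FALSE]) - 1) > 1e-9))
    msgs <- c(msgs, "freqs columns with nonzero totals must sum to 1")
  if (length(object@background) &&
      abs(sum(object@background) - 1) > 1e-6)
    msgs <- c(msgs, "background frequencies must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' KinasePSSM: peptide-library position-specific scoring matrix
#'
#' Per-kinase substrate preference scores from in vitro peptide-library
#' profiling: strictly positive preference odds for every (offset, residue)
#' cell over a contiguous offset range that must include +2.
#'
#' @slot kinase Kinase name.
#' @slot scores Numeric matrix, rows = the 20 residues, columns = signed
#'   offsets (as character column names, e.g. "-5".."4"), all entries > 0.
#' @export
setClass("KinasePSSM",
  representation(kinase = "character", scores = "matrix"))

setValidity("KinasePSSM", function(object) {
  msgs <- character(0)
  if (length(object@kinase) != 1L || !nzchar(object@kinase))
    msgs <- c(msgs, "kinase must be a single non-empty name")
  sc <- object@scores
  if (!identical(rownames(sc), AA20))
    msgs <- c(msgs, "score rows must be the 20-residue alphabet")
  if (any(!is.finite(sc)) || any(sc <= 0))
    msgs <- c(msgs, "all scores must be finite and > 0")
  pos <- suppressWarnings(as.integer(colnames(sc)))
  if (anyNA(pos) || !identical(pos, seq(min(pos), max(pos))))
    msgs <- c(msgs, "offset columns must be a contiguous integer range")
  else if (!2L %in% pos)
    msgs <- c(msgs, "offset range must include +2")
  if (length(msgs)) msgs else TRUE
})

#' PreferenceMatrix: normalized glutamate preference per kinase and position
#'
#' Rows are kinases, columns are signed offsets; each value is the
#' glutamate-preference score at that offset under the recorded
#' normalization, always in [0, 1].
#'
#' @slot values Numeric matrix kinase x offset, entries in [0, 1].
#' @slot normalization One of `"rank_quantile"`, `"row_max"`, `"log_odds_z"`.
#' @export
setClass("PreferenceMatrix",
  representation(values = "matrix", normalization = "character"))

setValidity("PreferenceMatrix", function(object) {
  msgs <- character(0)
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    msgs <- c(msgs, "values must lie in [0, 1]")
  if (!object@normalization %in% c("rank_quantile", "row_max", "log_odds_z"))
    msgs <- c(msgs, "unknown normalization")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic phosphoproteome generator
#'
#' See [simulationConfig()] for field meanings and defaults.
#' @export
setClass("SimulationConfig",
  representation(nProteins = "integer",
                 meanProteinLength = "integer",
                 compartmentMix = "numeric",
                 nSitesSecretory = "integer",
                 nSitesCytosol = "integer",
                 nSitesNuclear = "integer",
                 fEplus2 = "numeric",
                 serFraction = "numeric",
                 backgroundFreqs = "numeric",
                 nBackgroundPeptides = "integer",
                 membraneFraction = "numeric",
                 nonclassicalFraction = "numeric",
                 cytosolicMotifs = "logical",
                 nVariants = "integer",
                 variantMotifHitFraction = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  probs <- c(object@fEplus2, object@serFraction, object@membraneFraction,
             object@nonclassicalFraction, object@variantMotifHitFraction)
  if (any(probs < 0) || any(probs > 1))
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (abs(sum(object@backgroundFreqs) - 1) > 1e-9)
    msgs <- c(msgs, "backgroundFreqs must sum to 1 within 1e-9")
  if (!identical(names(object@backgroundFreqs), AA20))
    msgs <- c(msgs, "backgroundFreqs must be named by the 20-residue alphabet")
  if (abs(sum(object@compartmentMix) - 1) > 1e-9 ||
      any(object@compartmentMix < 0))
    msgs <- c(msgs, "compartmentMix must be a probability vector summing to 1")
  if (object@nProteins < 1L || object@meanProteinLength < 30L)
    msgs <- c(msgs, "need nProteins >= 1 and meanProteinLength >= 30")
  if (length(msgs)) msgs else TRUE
})

#' FilterConfig: substratome filter-cascade settings
#'
#' See [filterConfig()] for field meanings and defaults.
#' @export
setClass("FilterConfig",
  representation(compartmentWhitelist = "character",
                 requireCenter = "character",
                 requireEplus2 = "logical",
                 allowPSerPlus2 = "logical",
                 excludeNonclassical = "logical",
                 enforceTopology = "logical"))

setValidity("FilterConfig", function(object) {
  msgs <- character(0)
  if (length(object@compartmentWhitelist) == 0L)
    msgs <- c(msgs, "compartment whitelist must be non-empty")
  if (!object@requireCenter %in% c("S_only", "S_or_T"))
    msgs <- c(msgs, "requireCenter must be 'S_only' or 'S_or_T'")
  if (length(msgs)) msgs else TRUE
})
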