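#' Extract the sequence window around a phosphosite
#'
#' Returns the `2 * radius + 1`-mer centered on a 1-based protein position,
#' the unit of all motif statistics. Positions falling outside the protein
#' are filled with the pad character `"_"`, so pads appear only as a
#' contiguous prefix and/or suffix; pads are excluded from all downstream
#' frequency counts.
#'
#' @param protein A [ProteinSet-class] (the accession selects the sequence)
#'   or a single character sequence.
#' @param accession Accession within `protein` (ignored for character input).
#' @param position 1-based site position.
#' @param radius Window radius, default 7 (a 15-mer, offsets −7..+7).
#' @return A single character string of length `2 * radius + 1`.
#' @examples
#' extractWindow("MKTSAEQRL", position = 4)  # "____MKTSAEQRL__"
#' @export
extractWindow <- function(protein, accession = NULL, position, radius = 7L) {
  seqchr <- if (is(protein, "ProteinSet")) {
    if (is.null(accession) || !accession %in% names(protein@sequences))
      stop("unknown accession: ", accession)
    as.character(protein@sequences[[accession]])
  } else as.character(protein)
  n <- nchar(seqchr)
  if (position < 1L || position > n)
    stop("position ", position, " out of bounds for ",
         if (is.null(accession)) "sequence" else accession,
         " (length ", n, ")")
  lo <- position - radius
  hi <- position + radius
  core <- substr(seqchr, max(lo, 1L), min(hi, n))
  paste0(strrep(PAD_CHAR, max(0L, 1L - lo)),
         core,
         strrep(PAD_CHAR, max(0L, hi - n)))
}

#' Extract windows for a table of phosphosites
#'
#' Vectorized companion of [extractWindow()]: sites are first checked with
#' [validateSites()] (mismatching records dropped with a message), then a
#' window column is added.
#'
#' @param sites Phosphosite `data.frame` (see [readPhosphosites()]).
#' @param proteins A [ProteinSet-class].
#' @param radius Window radius, default 7.
#' @return `sites` with an added `window` character column.
#' @export
extractWindows <- function(sites, proteins, radius = 7L) {
  sites <- validateSites(sites, proteins)
  seqs <- as.character(proteins@sequences)
  sites$window <- vapply(seq_len(nrow(sites)), function(i) {
    extractWindow(seqs[[sites$accession[i]]], position = sites$position[i],
                  radius = radius)
  }, character(1))
  sites
}

#' Role of a protein position relative to an S-x-E phosphosite
#'
#' Classifies a query position against a motif site: the phosphoacceptor
#' serine itself (`"S_center"`), the +2 glutamate position (`"E_plus2"`), or
#' anything else (`"other"`). Both positions are 1-based on the same protein.
#'
#' @param sitePosition Position of the phosphosite serine.
#' @param queryPosition Position being classified (e.g. a missense variant).
#' @return `"S_center"`, `"E_plus2"` or `"other"` (vectorized).
#' @examples
#' motifRole(72, 74)  # "E_plus2"
#' motifRole(72, 72)  # "S_center"
#' @export
motifRole <- function(sitePosition, queryPosition) {
  ifelse(queryPosition == sitePosition, "S_center",
         ifelse(queryPosition == sitePosition + 2L, "E_plus2", "other"))
}

# Offset labels for a window of given radius: "-7".."7" with "0" the center.
windowOffsets <- function(radius = 7L) as.character(seq(-radius, radius))
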