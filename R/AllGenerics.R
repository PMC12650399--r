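#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet width
#' @importFrom stats pbinom phyper pnorm p.adjust setNames rbinom median
#' @importFrom utils read.delim write.table
NULL

#' Accessors for package containers
#'
#' `accessions()` returns accession identifiers; `sequences()` the
#' `AAStringSet`; `compartments()` a named list of compartment term vectors;
#' `topologySegments()` the topology table; `secretionRoute()` a named
#' character vector; `logoCounts()`, `logoFreqs()`, `logoHeightsMatrix()`,
#' `logoBackground()`, `bonferroniCutoff()` and `nWindows()` the LogoMatrix
#' slots; `preferenceValues()` the kinase-preference value matrix.
#'
#' @param x A package object (`ProteinSet`, `LogoMatrix`, `PreferenceMatrix`).
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setGeneric("topologySegments", function(x) standardGeneric("topologySegments"))
#' @rdname accessors
#' @export
setGeneric("secretionRoute", function(x) standardGeneric("secretionRoute"))
#' @rdname accessors
#' @export
setGeneric("logoCounts", function(x) standardGeneric("logoCounts"))
#' @rdname accessors
#' @export
setGeneric("logoFreqs", function(x) standardGeneric("logoFreqs"))
#' @rdname accessors
#' @export
setGeneric("logoHeightsMatrix", function(x) standardGeneric("logoHeightsMatrix"))
#' @rdname accessors
#' @export
setGeneric("logoBackground", function(x) standardGeneric("logoBackground"))
#' @rdname accessors
#' @export
setGeneric("bonferroniCutoff", function(x) standardGeneric("bonferroniCutoff"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("preferenceValues", function(x) standardGeneric("preferenceValues"))

#' @rdname accessors
#' @export
setMethod("accessions", "ProteinSet", function(x) names(x@sequences))
#' @rdname accessors
#' @export
setMethod("sequences", "ProteinSet", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("compartments", "ProteinSet", function(x) {
  out <- lapply(x@anno$compartments, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  })
  names(out) <- x@anno$accession
  out
})
#' @rdname accessors
#' @export
setMethod("topologySegments", "ProteinSet", function(x) x@topology)
#' @rdname accessors
#' @export
setMethod("secretionRoute", "ProteinSet",
          function(x) setNames(x@anno$secretion_route, x@anno$accession))

#' @rdname accessors
#' @export
setMethod("logoCounts", "LogoMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("logoFreqs", "LogoMatrix", function(x) x@freqs)
#' @rdname accessors
#' @export
setMethod("logoHeightsMatrix", "LogoMatrix", function(x) x@heights)
#' @rdname accessors
#' @export
setMethod("logoBackground", "LogoMatrix", function(x) x@background)
#' @rdname accessors
#' @export
setMethod("bonferroniCutoff", "LogoMatrix", function(x) x@bonferroni)
#' @rdname accessors
#' @export
setMethod("nWindows", "LogoMatrix", function(x) x@nWindows)
#' @rdname accessors
#' @export
setMethod("preferenceValues", "PreferenceMatrix", function(x) x@values)

setMethod("show", "ProteinSet", function(object) {
  n <- length(object@sequences)
  cat("ProteinSet with", n, "proteins\n")
  cat("  lengths:", paste(range(Biostrings::width(object@sequences)),
                          collapse = "-"), "aa\n")
  cat("  membrane (with topology):",
      length(unique(object@topology$accession)), "\n")
  rt <- table(object@anno$secretion_route)
  cat("  secretion route:",
      paste(names(rt), rt, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LogoMatrix", function(object) {
  cat("LogoMatrix over", object@nWindows, "windows,",
      ncol(object@counts), "positions\n")
  cc <- object@centerComposition
  if (length(cc))
    cat("  center composition:",
        paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  if (length(object@heights)) {
    cat("  Bonferroni threshold (-log10):",
        format(object@bonferroni, digits = 4), "\n")
    sig <- significantCells(object)
    cat("  significant cells:", nrow(sig), "\n")
  } else cat("  heights: not computed (counts/freqs only)\n")
})

setMethod("show", "KinasePSSM", function(object) {
  cat("KinasePSSM for", object@kinase, "- offsets",
      paste(range(as.integer(colnames(object@scores))), collapse = ".."), "\n")
})

setMethod("show", "PreferenceMatrix", function(object) {
  cat("PreferenceMatrix:", nrow(object@values), "kinases x",
      ncol(object@values), "positions (", object@normalization, ")\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nProteins, " proteins, sites ",
      object@nSitesSecretory, "/", object@nSitesCytosol, "/",
      object@nSitesNuclear, " (secretory/cytosol/nuclear), f(E@+2)=",
      object@fEplus2, ", seed=", object@seed, "\n", sep = "")
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: center=", object@requireCenter,
      ", E@+2=", object@requireEplus2,
      ", topology=", object@enforceTopology,
      ", exclude non-classical=", object@excludeNonclassical, "\n", sep = "")
  cat("  whitelist:", paste(object@compartmentWhitelist, collapse = "; "),
      "\n")
})
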