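#' Substratome filter-cascade configuration
#'
#' Settings for [applyFilters()]. The defaults encode the curation rules for
#' a luminal S-x-E substratome: luminal/extracellular compartment whitelist,
#' serine-only phosphoacceptor, glutamate required at +2, membrane-topology
#' enforcement, and exclusion of proteins reaching the extracellular space by
#' non-classical secretion.
#'
#' @param compartmentWhitelist Compartment terms (matched case-insensitively)
#'   that admit a protein.
#' @param requireCenter `"S_only"` (default) or `"S_or_T"`.
#' @param requireEplus2 Require glutamate at +2, default TRUE.
#' @param allowPSerPlus2 Treat an annotated phospho-serine at +2 as
#'   satisfying the acidic +2 requirement, default FALSE (strict S-x-E).
#' @param excludeNonclassical Reject proteins flagged as non-classically
#'   secreted, default TRUE.
#' @param enforceTopology For membrane proteins, require the site to fall in
#'   a luminal/extracellular segment, default TRUE.
#' @return A validated [FilterConfig-class].
#' @export
filterConfig <- function(compartmentWhitelist = c("Golgi lumen",
                                                  "endoplasmic reticulum lumen",
                                                  "extracellular matrix",
                                                  "extracellular region",
                                                  "extracellular space"),
                         requireCenter = "S_only",
                         requireEplus2 = TRUE,
                         allowPSerPlus2 = FALSE,
                         excludeNonclassical = TRUE,
                         enforceTopology = TRUE) {
  new("FilterConfig",
      compartmentWhitelist = compartmentWhitelist,
      requireCenter = requireCenter,
      requireEplus2 = requireEplus2,
      allowPSerPlus2 = allowPSerPlus2,
      excludeNonclassical = excludeNonclassical,
      enforceTopology = enforceTopology)
}

#' Apply the substratome filter cascade
#'
#' Filters phosphosite records down to the putative substratome. Rules run in
#' a fixed order so each rejection carries a deterministic, single reason —
#' the first failing rule:
#'
#' 1. `center_residue` — phosphoacceptor must be Ser (or Ser/Thr).
#' 2. `motif` — glutamate at +2 (the "x" at +1 is unconstrained; a site with
#'    no +2 residue cannot match; optionally an annotated phospho-Ser at +2
#'    also satisfies the requirement).
#' 3. `compartment` — at least one whitelisted compartment term
#'    (case-insensitive); proteins carrying both whitelisted and cytosolic
#'    terms are admitted here and left to the topology/secretion rules.
#' 4. `topology` — for proteins with topology segments, the site must not lie
#'    in a cytoplasmic or transmembrane segment; membrane sites not covered
#'    by any segment are kept but flagged (`topology_warning`), surfacing the
#'    ambiguity instead of guessing.
#' 5. `secretion_route` — non-classically secreted proteins are rejected.
#'
#' Sites whose accession has no protein entry are rejected with reason
#' `"unmapped"`; kept entries are deduplicated on (accession, position).
#'
#' @param sites Phosphosite `data.frame` (see [readPhosphosites()]).
#' @param proteins A [ProteinSet-class].
#' @param config A [FilterConfig-class], default [filterConfig()].
#' @return A list with `kept` (data.frame: `accession`, `gene`, `position`,
#'   `residue`, `window`, `compartments_matched`, `evidence`, `novelty`,
#'   `topology_warning`) sorted by accession then position, and `rejected`
#'   (data.frame of the input rows plus a `reason` column).
#' @export
applyFilters <- function(sites, proteins, config = filterConfig()) {
  stopifnot(is(config, "FilterConfig"))
  sites <- sites[!duplicated(sites[c("accession", "position")]), ,
                 drop = FALSE]
  seqs <- as.character(proteins@sequences)
  comps <- compartments(proteins)
  route <- secretionRoute(proteins)
  topo <- proteins@topology
  genes <- setNames(proteins@anno$gene, proteins@anno$accession)
  wl <- tolower(trimws(config@compartmentWhitelist))
  siteKey <- paste(sites$accession, sites$position)

  n <- nrow(sites)
  reason <- rep(NA_character_, n)
  warnFlag <- logical(n)
  window <- rep(NA_character_, n)
  matched <- rep("", n)

  for (i in seq_len(n)) {
    acc <- sites$accession[i]
    pos <- sites$position[i]
    if (!acc %in% names(seqs)) { reason[i] <- "unmapped"; next }
    sq <- seqs[[acc]]
    len <- nchar(sq)
    if (pos < 1L || pos > len) { reason[i] <- "unmapped"; next }
    res <- substr(sq, pos, pos)
    # 1. center residue
    okCenter <- if (config@requireCenter == "S_only") res == "S"
                else res %in% c("S", "T")
    if (!okCenter) { reason[i] <- "center_residue"; next }
    # 2. motif: the +2 residue must exist and be E (or annotated pSer)
    if (config@requireEplus2) {
      if (pos + 2L > len) { reason[i] <- "motif"; next }
      plus2 <- substr(sq, pos + 2L, pos + 2L)
      okMotif <- plus2 == "E" ||
        (config@allowPSerPlus2 && plus2 == "S" &&
           paste(acc, pos + 2L) %in% siteKey)
      if (!okMotif) { reason[i] <- "motif"; next }
    }
    # 3. compartment whitelist
    hit <- comps[[acc]][tolower(comps[[acc]]) %in% wl]
    if (!length(hit)) { reason[i] <- "compartment"; next }
    matched[i] <- paste(sort(hit), collapse = ";")
    # 4. membrane topology
    if (config@enforceTopology) {
      seg <- topo[topo$accession == acc, , drop = FALSE]
      if (nrow(seg)) {
        inSeg <- seg$side[pos >= seg$start & pos <= seg$end]
        if (length(inSeg) && inSeg[1L] != "luminal_or_extracellular") {
          reason[i] <- "topology"; next
        }
        if (!length(inSeg)) warnFlag[i] <- TRUE
      }
    }
    # 5. secretion route
    if (config@excludeNonclassical && route[[acc]] == "non_classical") {
      reason[i] <- "secretion_route"; next
    }
    window[i] <- extractWindow(sq, position = pos)
  }

  keep <- is.na(reason)
  novelty <- c(validated_direct = "known_direct",
               ko_responsive = "ko_responsive",
               large_scale = "novel")[sites$evidence]
  novelty[is.na(novelty)] <- "novel"
  kept <- data.frame(accession = sites$accession[keep],
                     gene = unname(genes[sites$accession[keep]]),
                     position = sites$position[keep],
                     residue = sites$residue[keep],
                     window = window[keep],
                     compartments_matched = matched[keep],
                     evidence = sites$evidence[keep],
                     novelty = unname(novelty[keep]),
                     topology_warning = warnFlag[keep],
                     stringsAsFactors = FALSE)
  kept <- kept[order(kept$accession, kept$position), , drop = FALSE]
  rownames(kept) <- NULL
  rejected <- sites[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rejected <- rejected[order(rejected$accession, rejected$position), ,
                       drop = FALSE]
  rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Compare a putative substratome against validated substrate lists
#'
#' The novelty comparison behind a validated-vs-putative Venn diagram: how
#' many putative sites (and proteins) were already known as substrates, and
#' how many are novel. Fractions are rounded to one decimal on the percent
#' scale.
#'
#' @param putative Kept substratome `data.frame` from [applyFilters()].
#' @param validatedSites `data.frame` with columns `accession`, `position`
#'   (known substrate sites), or a character vector of `"accession:position"`.
#' @param validatedProteins Character vector of known substrate accessions;
#'   defaults to the accessions of `validatedSites`.
#' @return A list: `site_total`, `site_overlap`, `site_novel`,
#'   `site_novel_pct`, `protein_total`, `protein_overlap`, `protein_novel`,
#'   `protein_novel_pct`.
#' @export
compareToValidated <- function(putative, validatedSites,
                               validatedProteins = NULL) {
  vkeys <- if (is.data.frame(validatedSites))
    paste(validatedSites$accession, validatedSites$position, sep = ":")
  else as.character(validatedSites)
  if (is.null(validatedProteins))
    validatedProteins <- unique(sub(":.*$", "", vkeys))
  pkeys <- unique(paste(putative$accession, putative$position, sep = ":"))
  paccs <- unique(putative$accession)
  siteOverlap <- sum(pkeys %in% vkeys)
  protOverlap <- sum(paccs %in% validatedProteins)
  pct <- function(x, n) if (n == 0L) 0 else round(100 * x / n, 1L)
  list(site_total = length(pkeys),
       site_overlap = siteOverlap,
       site_novel = length(pkeys) - siteOverlap,
       site_novel_pct = pct(length(pkeys) - siteOverlap, length(pkeys)),
       protein_total = length(paccs),
       protein_overlap = protOverlap,
       protein_novel = length(paccs) - protOverlap,
       protein_novel_pct = pct(length(paccs) - protOverlap, length(paccs)))
}

#' Summarize a substratome
#'
#' @param kept Kept substratome `data.frame` from [applyFilters()].
#' @return A list: `n_sites`, `n_proteins`, `compartment_tally` (named
#'   integer vector over matched terms), `e_plus2_fraction` (fraction of kept
#'   windows with glutamate at offset +2; 1 under the default filter config),
#'   `center_composition`.
#' @export
summarizeSubstratome <- function(kept) {
  if (nrow(kept) == 0L)
    return(list(n_sites = 0L, n_proteins = 0L,
                compartment_tally = integer(0), e_plus2_fraction = NA_real_,
                center_composition = c(S = 0L, T = 0L)))
  terms <- unlist(strsplit(kept$compartments_matched, ";", fixed = TRUE))
  terms <- terms[nzchar(terms)]
  plus2 <- substr(kept$window, 10L, 10L)  # offset +2 in a radius-7 window
  cc <- table(factor(kept$residue, levels = c("S", "T")))
  list(n_sites = nrow(kept),
       n_proteins = length(unique(kept$accession)),
       compartment_tally = sort(table(terms), decreasing = TRUE),
       e_plus2_fraction = mean(plus2 == "E"),
       center_composition = setNames(as.integer(cc), names(cc)))
}

#' Write substratome and rejection tables to TSV
#'
#' @param result The list returned by [applyFilters()].
#' @param keptPath,rejectedPath Output TSV paths.
#' @return Invisibly, the paths written.
#' @export
writeSubstratome <- function(result, keptPath, rejectedPath = NULL) {
  write.table(result$kept, keptPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(rejectedPath))
    write.table(result$rejected, rejectedPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(keptPath, rejectedPath))
}
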