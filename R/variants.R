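#' Parse protein-level HGVS missense notation
#'
#' Accepts three-letter (`p.Ser72Pro`) and one-letter (`p.S72P`) forms, with
#' or without the `p.` prefix. Positions are 1-based canonical protein
#' coordinates.
#'
#' @param x Character vector of HGVS protein strings.
#' @return A `data.frame` with columns `ref_aa`, `protein_position`,
#'   `alt_aa` (one-letter codes).
#' @examples
#' parseHgvsP(c("p.Ser72Pro", "p.E74A"))
#' @export
parseHgvsP <- function(x) {
  body <- sub("^p\\.", "", x)
  m3 <- regmatches(body, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$",
                                 body))
  m1 <- regmatches(body, regexec("^([A-Z])([0-9]+)([A-Z])$", body))
  three2one <- setNames(names(AA_THREE), AA_THREE)
  parseOne <- function(i) {
    if (length(m3[[i]]) == 4L) {
      ref <- three2one[m3[[i]][2L]]
      alt <- three2one[m3[[i]][4L]]
      if (is.na(ref) || is.na(alt))
        stop("unknown residue code in HGVS: ", x[i])
      c(ref, m3[[i]][3L], alt)
    } else if (length(m1[[i]]) == 4L) {
      if (!m1[[i]][2L] %in% AA20 || !m1[[i]][4L] %in% AA20)
        stop("unknown residue code in HGVS: ", x[i])
      m1[[i]][c(2L, 3L, 4L)]
    } else stop("cannot parse HGVS protein notation: ", x[i])
  }
  parts <- vapply(seq_along(x), parseOne, character(3))
  data.frame(ref_aa = unname(parts[1L, ]),
             protein_position = as.integer(parts[2L, ]),
             alt_aa = unname(parts[3L, ]),
             stringsAsFactors = FALSE)
}

#' Format a missense change as three-letter HGVS
#'
#' @param ref,alt One-letter residue codes.
#' @param position 1-based protein position.
#' @return Character vector like `"p.Ser72Pro"`.
#' @export
formatHgvsP <- function(ref, position, alt) {
  paste0("p.", AA_THREE[ref], position, AA_THREE[alt])
}

#' Screen clinical variants against substratome motif positions
#'
#' Intersects missense variants with the S-x-E motifs of a substratome:
#' a variant hits a site when it falls on the phosphoacceptor serine
#' (`S_center`) or on the +2 glutamate (`E_plus2`) of a kept substratome
#' entry on the same protein, and its clinical classification is in
#' `classes`. When sequences are available, the variant's reference residue
#' is cross-checked; mismatching hits are flagged `ref_mismatch = TRUE` and
#' excluded from the main report by [writeHitReport()]. The same variant
#' carried with conflicting classifications across submissions yields one
#' row per submission, flagged `conflict = TRUE`.
#'
#' @param variants Variant `data.frame` (see [readVariants()]).
#' @param substratome Kept substratome `data.frame` from [applyFilters()].
#' @param classes Clinical classes to report, default pathogenic and
#'   likely_pathogenic.
#' @param proteins Optional [ProteinSet-class] for reference-residue checks.
#' @return A `data.frame` with columns `gene`, `accession`, `hgvs_p`,
#'   `site_position`, `role`, `classification`, `condition`, `conflict`,
#'   `ref_mismatch`, sorted by accession then variant position; attribute
#'   `"n_unmatched"` counts variants on proteins absent from the substratome.
#' @export
screenVariants <- function(variants, substratome,
                           classes = c("pathogenic", "likely_pathogenic"),
                           proteins = NULL) {
  inSub <- variants$accession %in% substratome$accession
  nUnmatched <- sum(!inSub)
  v <- variants[inSub & variants$classification %in% classes, , drop = FALSE]
  rows <- list()
  if (nrow(v)) {
    seqs <- if (!is.null(proteins)) as.character(proteins@sequences) else NULL
    vkey <- paste(variants$accession, variants$hgvs_p)
    conflictKeys <- unique(vkey[duplicated(vkey)])
    multiClass <- vapply(split(variants$classification, vkey),
                         function(cl) length(unique(cl)) > 1L, logical(1))
    for (i in seq_len(nrow(v))) {
      sites <- substratome[substratome$accession == v$accession[i], ,
                           drop = FALSE]
      role <- motifRole(sites$position, v$protein_position[i])
      hit <- which(role != "other")
      for (j in hit) {
        mismatch <- FALSE
        if (!is.null(seqs) && v$accession[i] %in% names(seqs)) {
          actual <- substr(seqs[[v$accession[i]]], v$protein_position[i],
                           v$protein_position[i])
          mismatch <- actual != v$ref_aa[i]
        }
        key <- paste(v$accession[i], v$hgvs_p[i])
        rows[[length(rows) + 1L]] <- data.frame(
          gene = v$gene[i], accession = v$accession[i],
          hgvs_p = v$hgvs_p[i],
          variant_position = v$protein_position[i],
          site_position = sites$position[j],
          role = role[j],
          classification = v$classification[i],
          condition = v$condition[i],
          conflict = key %in% conflictKeys && isTRUE(multiClass[[key]]),
          ref_mismatch = mismatch,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene = character(0), accession = character(0),
                  hgvs_p = character(0), variant_position = integer(0),
                  site_position = integer(0), role = character(0),
                  classification = character(0), condition = character(0),
                  conflict = logical(0), ref_mismatch = logical(0),
                  stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$variant_position, out$site_position,
                   out$hgvs_p, out$classification), , drop = FALSE]
  out <- out[!duplicated(out[c("accession", "hgvs_p", "site_position",
                               "classification")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- nUnmatched
  out
}

#' Write the motif-hit report
#'
#' Emits the stable-sorted TSV of motif hits (columns `gene`, `accession`,
#' `variant` in HGVS p. notation, `role`, `classification`, `condition`,
#' `conflict`); rows flagged `ref_mismatch` are excluded from the main
#' report. With zero hits a header-only file is written.
#'
#' @param hits `data.frame` from [screenVariants()].
#' @param path Output TSV path.
#' @return Invisibly, the reported `data.frame`.
#' @export
writeHitReport <- function(hits, path) {
  rep <- hits[!hits$ref_mismatch, , drop = FALSE]
  out <- data.frame(gene = rep$gene, accession = rep$accession,
                    variant = rep$hgvs_p, role = rep$role,
                    classification = rep$classification,
                    condition = rep$condition, conflict = rep$conflict,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
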