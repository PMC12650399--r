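#' Read a protein set from FASTA plus annotation tables
#'
#' Sequences come from a FASTA file (headers are taken up to the first
#' whitespace and used as accessions). Annotations come from a tab-separated
#' table with columns `accession`, `gene`, `compartments` (semicolon-separated
#' terms, may be empty) and `secretion_route`; membrane-topology segments from
#' an optional second table with columns `accession`, `start`, `end`, `side`.
#' Unknown compartment terms are preserved verbatim — the vocabulary is an
#' open set matched case-insensitively by the filter cascade. Annotation rows
#' referencing accessions absent from the FASTA are dropped with a warning;
#' FASTA entries without an annotation row get empty compartments and
#' `secretion_route = "none"`.
#'
#' @param fasta Path to a FASTA file of amino-acid sequences.
#' @param annotations Path to the annotation TSV, or `NULL` for none.
#' @param topology Path to the topology TSV, or `NULL` for none.
#' @return A [ProteinSet-class].
#' @examples
#' dir <- tempdir()
#' writeLines(c(">P1", "MKTSAEQRL"), file.path(dir, "p.fasta"))
#' writeLines(c("accession\tgene\tcompartments\tsecretion_route",
#'              "P1\tG1\textracellular region\tclassical"),
#'            file.path(dir, "p.tsv"))
#' ps <- readProteins(file.path(dir, "p.fasta"), file.path(dir, "p.tsv"))
#' accessions(ps)
#' @export
readProteins <- function(fasta, annotations = NULL, topology = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  anno <- if (!is.null(annotations)) {
    read.delim(annotations, stringsAsFactors = FALSE,
               colClasses = "character")
  } else {
    data.frame(accession = character(0), gene = character(0),
               compartments = character(0), secretion_route = character(0),
               stringsAsFactors = FALSE)
  }
  for (col in c("gene", "compartments", "secretion_route"))
    if (!col %in% names(anno)) anno[[col]] <- ""
  missing <- setdiff(anno$accession, names(seqs))
  if (length(missing)) {
    warning("dropping ", length(missing),
            " annotation row(s) referencing absent accessions: ",
            paste(utils::head(missing, 5L), collapse = ", "))
    anno <- anno[!anno$accession %in% missing, , drop = FALSE]
  }
  extra <- setdiff(names(seqs), anno$accession)
  if (length(extra))
    anno <- rbind(anno[, c("accession", "gene", "compartments",
                           "secretion_route")],
                  data.frame(accession = extra, gene = "", compartments = "",
                             secretion_route = "none",
                             stringsAsFactors = FALSE))
  anno$secretion_route[!nzchar(anno$secretion_route)] <- "none"
  topo <- if (!is.null(topology)) {
    tt <- read.delim(topology, stringsAsFactors = FALSE)
    tt$start <- as.integer(tt$start)
    tt$end <- as.integer(tt$end)
    tt
  } else {
    data.frame(accession = character(0), start = integer(0),
               end = integer(0), side = character(0),
               stringsAsFactors = FALSE)
  }
  newProteinSet(seqs, anno, topo)
}

#' Construct a ProteinSet from in-memory pieces
#'
#' @param sequences Named `AAStringSet` or named character vector.
#' @param anno Annotation `data.frame` (see [readProteins()]); missing
#'   columns are filled with defaults.
#' @param topology Topology `data.frame`, default empty.
#' @return A validated [ProteinSet-class].
#' @export
newProteinSet <- function(sequences, anno = NULL, topology = NULL) {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  if (is.null(anno))
    anno <- data.frame(accession = names(sequences),
                       stringsAsFactors = FALSE)
  for (col in c("gene", "compartments"))
    if (!col %in% names(anno)) anno[[col]] <- ""
  if (!"secretion_route" %in% names(anno)) anno$secretion_route <- "none"
  if (is.null(topology))
    topology <- data.frame(accession = character(0), start = integer(0),
                           end = integer(0), side = character(0),
                           stringsAsFactors = FALSE)
  anno <- anno[order(anno$accession), , drop = FALSE]
  rownames(anno) <- NULL
  sequences <- sequences[order(names(sequences))]
  new("ProteinSet", sequences = sequences, anno = anno, topology = topology)
}

#' Write a ProteinSet back to FASTA + TSV
#'
#' Deterministic output: rows sorted by accession, then start position for
#' topology. Re-reading the files reconstructs an identical object.
#'
#' @param proteins A [ProteinSet-class].
#' @param fasta,annotations,topology Output paths (`topology` optional).
#' @return Invisibly, the paths written.
#' @export
writeProteins <- function(proteins, fasta, annotations, topology = NULL) {
  seqs <- proteins@sequences[order(names(proteins@sequences))]
  Biostrings::writeXStringSet(seqs, fasta)
  anno <- proteins@anno[order(proteins@anno$accession), , drop = FALSE]
  write.table(anno[, c("accession", "gene", "compartments",
                       "secretion_route")],
              annotations, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(topology)) {
    topo <- proteins@topology
    topo <- topo[order(topo$accession, topo$start), , drop = FALSE]
    write.table(topo, topology, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta, annotations, topology))
}

#' Read and write phosphosite tables
#'
#' Phosphosites travel as a `data.frame` with columns `accession`, `position`
#' (1-based), `residue` (`"S"`/`"T"`), `evidence` (`"large_scale"`,
#' `"validated_direct"`, `"ko_responsive"`) and `source_compartment_terms`
#' (semicolon-separated, may be empty). `writePhosphosites()` emits rows
#' sorted by accession then position.
#'
#' @param path TSV path.
#' @param sites Phosphosite `data.frame`.
#' @return `readPhosphosites()`: the `data.frame`.
#' @export
readPhosphosites <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(position = "integer"))
  need <- c("accession", "position", "residue")
  if (!all(need %in% names(x)))
    stop("phosphosite table must have columns ",
         paste(need, collapse = ", "))
  if (!"evidence" %in% names(x)) x$evidence <- "large_scale"
  if (!"source_compartment_terms" %in% names(x))
    x$source_compartment_terms <- ""
  bad <- setdiff(x$residue, c("S", "T"))
  if (length(bad)) stop("phosphosite residues must be S or T, found: ",
                        paste(bad, collapse = ","))
  x[, c("accession", "position", "residue", "evidence",
        "source_compartment_terms")]
}

#' @rdname readPhosphosites
#' @export
writePhosphosites <- function(sites, path) {
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check phosphosite records against protein sequences
#'
#' Records whose accession is absent from the protein set, whose position
#' falls outside the sequence, or whose annotated residue does not match the
#' sequence character at that position are dropped with a message — mismatches
#' are treated as curation errors, never silently corrected.
#'
#' @param sites Phosphosite `data.frame` (see [readPhosphosites()]).
#' @param proteins A [ProteinSet-class].
#' @return The validated subset of `sites`, with a `"dropped"` attribute
#'   holding the rejected rows and a `reason` column.
#' @export
validateSites <- function(sites, proteins) {
  seqs <- as.character(proteins@sequences)
  reason <- rep(NA_character_, nrow(sites))
  known <- sites$accession %in% names(seqs)
  reason[!known] <- "unmapped"
  idx <- which(known)
  if (length(idx)) {
    lens <- nchar(seqs)[sites$accession[idx]]
    oob <- sites$position[idx] < 1L | sites$position[idx] > lens
    reason[idx[oob]] <- "position_out_of_bounds"
    chk <- idx[!oob]
    if (length(chk)) {
      actual <- substr(seqs[sites$accession[chk]],
                       sites$position[chk], sites$position[chk])
      reason[chk[actual != sites$residue[chk]]] <- "residue_mismatch"
    }
  }
  dropped <- sites[!is.na(reason), , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- reason[!is.na(reason)]
    message("validateSites: dropping ", nrow(dropped), " record(s) (",
            paste(names(table(dropped$reason)), table(dropped$reason),
                  sep = "=", collapse = ", "), ")")
  }
  out <- sites[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Read and write clinical missense-variant tables
#'
#' A ClinVar-export-like dialect: tab-separated with columns `gene`,
#' `accession` (UniProt-style), `hgvs_p` (protein HGVS, e.g. `p.Ser72Pro` or
#' `p.S72P`), `classification` (`pathogenic`, `likely_pathogenic`,
#' `uncertain`, `benign`, `likely_benign`) and `condition` (free text).
#' Reading parses HGVS into `protein_position`, `ref_aa`, `alt_aa` columns.
#'
#' @param path TSV path.
#' @param variants Variant `data.frame`.
#' @return `readVariants()`: the parsed `data.frame`.
#' @export
readVariants <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "accession", "hgvs_p", "classification", "condition")
  if (!all(need %in% names(x)))
    stop("variant table must have columns ", paste(need, collapse = ", "))
  parsed <- parseHgvsP(x$hgvs_p)
  cbind(x[need], parsed)
}

#' @rdname readVariants
#' @export
writeVariants <- function(variants, path) {
  cols <- c("gene", "accession", "hgvs_p", "classification", "condition")
  v <- variants[order(variants$accession, variants$protein_position),
                cols, drop = FALSE]
  write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
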