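#' Motif conservation at an S-x-E site across a multiple sequence alignment
#'
#' Given a pre-built alignment containing a reference sequence, maps a
#' 1-based ungapped site position on the reference to its alignment column,
#' finds the column holding the reference's +2 residue, and reports the
#' fraction of sequences conserving the phosphoacceptor (S, or S/T when
#' `matchST = TRUE`) at the site column and glutamate at the +2 column.
#' Fractions are over the sequences that are not gapped at the respective
#' column, so a sparse alignment edge does not deflate conservation.
#'
#' @param msa Path to an aligned FASTA file, or a named character vector of
#'   aligned (equal-length, gap `"-"`) sequences.
#' @param referenceId Name of the reference sequence in the alignment.
#' @param sitePosition 1-based position of the site in the *ungapped*
#'   reference sequence.
#' @param matchST Count Thr as conserving the phosphoacceptor, default FALSE.
#' @return Named numeric vector `c(fraction_S_conserved,
#'   fraction_E_plus2_conserved)`.
#' @export
msaMotifConservation <- function(msa, referenceId, sitePosition,
                                 matchST = FALSE) {
  if (length(msa) == 1L && file.exists(msa)) {
    aln <- Biostrings::readAAStringSet(msa)
    seqs <- as.character(aln)
    names(seqs) <- sub("\\s.*$", "", names(aln))
  } else seqs <- setNames(as.character(msa), names(msa))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment sequences must all have the same length")
  if (!referenceId %in% names(seqs))
    stop("reference sequence not found: ", referenceId)
  ref <- strsplit(seqs[[referenceId]], "", fixed = TRUE)[[1L]]
  ungapped <- which(ref != "-")
  if (sitePosition < 1L || sitePosition + 2L > length(ungapped))
    stop("reference has no +2 residue for ungapped position ", sitePosition,
         " (ungapped length ", length(ungapped), ")")
  siteCol <- ungapped[sitePosition]
  plus2Col <- ungapped[sitePosition + 2L]
  colChars <- function(col) vapply(seqs, substr, character(1), col, col)
  sCol <- colChars(siteCol)
  eCol <- colChars(plus2Col)
  sOk <- sCol != "-"
  eOk <- eCol != "-"
  if (!any(sOk) || !any(eOk))
    stop("mapped column is gap-only")
  sMatch <- if (matchST) sCol %in% c("S", "T") else sCol == "S"
  c(fraction_S_conserved = sum(sMatch & sOk) / sum(sOk),
    fraction_E_plus2_conserved = sum(eCol == "E" & eOk) / sum(eOk))
}
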