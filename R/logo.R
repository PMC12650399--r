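#' Signed binomial-tail significance (probability-logo height)
#'
#' The probability-logo statistic for one (position, residue) cell: with `k`
#' occurrences of the residue among `n` non-pad characters at that position
#' and background residue probability `pBg`, the height is
#' `-log10 P(K >= k)` when the residue is at or above its background rate
#' (`k/n >= pBg`; positive = over-represented) and `+log10 P(K <= k)`
#' otherwise (a negative number; under-represented), with
#' `K ~ Binomial(n, pBg)`. Tails are exact binomial sums — no normal
#' approximation — computed in log space so extreme enrichments keep
#' precision.
#'
#' @param k Residue count, `0 <= k <= n` (vectorized).
#' @param n Column total (non-pad characters).
#' @param pBg Background probability, strictly inside (0, 1).
#' @return Signed height(s) on the log10 scale.
#' @examples
#' binomialHeight(10, 10, 0.05)  # 13.0103: P = 0.05^10
#' binomialHeight(0, 10, 0.5)    # -3.0103: P = 0.5^10
#' @export
binomialHeight <- function(k, n, pBg) {
  if (any(pBg <= 0) || any(pBg >= 1))
    stop("background probability must be strictly inside (0, 1)")
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  m <- max(length(k), length(n), length(pBg))
  k <- rep_len(k, m); n <- rep_len(n, m); pBg <- rep_len(pBg, m)
  upper <- k / n >= pBg
  h <- numeric(m)
  if (any(upper)) {
    lp <- pbinom(k[upper] - 1L, n[upper], pBg[upper],
                 lower.tail = FALSE, log.p = TRUE)
    h[upper] <- -lp / log(10)
  }
  if (any(!upper)) {
    lp <- pbinom(k[!upper], n[!upper], pBg[!upper], log.p = TRUE)
    h[!upper] <- lp / log(10)
  }
  h
}

#' Bonferroni-corrected significance threshold on the -log10 scale
#'
#' `-log10(alpha / (nPositions * nResidues))`: a residue height is called
#' significant when its magnitude exceeds this cutoff. The default testing
#' family for a radius-7 logo is 14 non-center positions x 20 residues = 280
#' cells.
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param nPositions Number of tested positions (center excluded).
#' @param nResidues Number of residues tested per position, default 20.
#' @return The threshold (>= 0).
#' @examples
#' bonferroniThreshold(0.05, 14)  # 3.7482
#' @export
bonferroniThreshold <- function(alpha, nPositions, nResidues = 20L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  -log10(alpha / (nPositions * nResidues))
}

#' Position-specific residue counts and frequencies for a window set
#'
#' Tallies residues at each signed offset over a set of equal-length windows.
#' Pad characters are excluded from column totals, so a column's frequencies
#' are over the windows that actually cover that offset; an all-pad column
#' has total 0 and `NaN` frequencies (reported as missing). The center column
#' is tallied like the rest but additionally summarized as the S/T center
#' composition; it is excluded from significance testing by [logoHeights()].
#'
#' @param windows Character vector of equal-length windows (odd length), or a
#'   `data.frame` with a `window` column.
#' @return A [LogoMatrix-class] with counts and frequencies (heights empty
#'   until [logoHeights()] is applied).
#' @export
countMatrix <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) == 0L) stop("no windows supplied")
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L) stop("windows must all have the same length")
  if (wlen %% 2L != 1L) stop("window length must be odd")
  radius <- (wlen - 1L) %/% 2L
  mat <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                nrow = wlen)
  offs <- windowOffsets(radius)
  counts <- vapply(seq_len(wlen), function(j) {
    tabulate(factor(mat[j, ], levels = AA20), nbins = 20L)
  }, integer(20L))
  dimnames(counts) <- list(AA20, offs)
  tot <- colSums(counts)
  freqs <- sweep(counts, 2L, tot, "/")  # NaN where tot == 0
  center <- mat[radius + 1L, ]
  cc <- table(factor(center, levels = c("S", "T")))
  new("LogoMatrix", nWindows = length(windows),
      counts = counts, freqs = freqs,
      heights = matrix(numeric(0), 0, 0),
      background = numeric(0), bonferroni = NA_real_,
      centerComposition = setNames(as.integer(cc), names(cc)))
}

#' Pooled background residue frequencies from background windows
#'
#' Position-independent frequencies pooled over all columns of a set of
#' background windows (the probability-logo default), with add-nothing
#' plain maximum-likelihood estimation. Residues never observed would give
#' degenerate binomial tails, so frequencies are floored at `floor` and
#' renormalized.
#'
#' @param background Character vector of background windows, or a named
#'   frequency vector over [AA20] (returned normalized).
#' @param floor Minimum frequency, default `1e-4`.
#' @return Named numeric vector over [AA20], summing to 1.
#' @export
backgroundFrequencies <- function(background, floor = 1e-4) {
  if (is.numeric(background)) {
    f <- background[AA20]
    if (anyNA(f)) stop("background frequencies must cover the 20 residues")
  } else {
    if (is.data.frame(background)) background <- background$window
    ch <- unlist(strsplit(background, "", fixed = TRUE), use.names = FALSE)
    ch <- ch[ch != PAD_CHAR]
    f <- tabulate(factor(ch, levels = AA20), nbins = 20L)
    names(f) <- AA20
  }
  f <- pmax(f / sum(f), floor)
  f / sum(f)
}

#' Compute signed significance heights for a LogoMatrix
#'
#' Applies [binomialHeight()] to every (offset, residue) cell against
#' position-independent background frequencies and stores the Bonferroni
#' threshold for the tested family: all non-center positions x 20 residues.
#' The center column's heights are set to 0 (it is reported descriptively
#' only — strata are split by center residue before analysis, so testing the
#' center would be circular). Columns with zero total (all-pad) get height 0.
#'
#' @param x A [LogoMatrix-class] from [countMatrix()].
#' @param background Background windows or frequency vector (see
#'   [backgroundFrequencies()]).
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return The [LogoMatrix-class] with `heights`, `background` and
#'   `bonferroni` filled in.
#' @export
logoHeights <- function(x, background, alpha = 0.05) {
  stopifnot(is(x, "LogoMatrix"))
  bg <- backgroundFrequencies(background)
  counts <- x@counts
  tot <- colSums(counts)
  offs <- as.integer(colnames(counts))
  heights <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in which(tot > 0L & offs != 0L))
    heights[, j] <- binomialHeight(counts[, j], tot[j], bg)
  x@heights <- heights
  x@background <- bg
  x@bonferroni <- bonferroniThreshold(alpha, sum(offs != 0L), 20L)
  x
}

#' Significant logo cells beyond the Bonferroni threshold
#'
#' Cells whose absolute height exceeds the stored Bonferroni cutoff, sorted
#' by decreasing `|height|`; exact ties broken by (position, residue)
#' lexicographic order.
#'
#' @param x A [LogoMatrix-class] with heights computed.
#' @return A `data.frame` with columns `position` (integer offset), `residue`
#'   and `height` (possibly zero rows).
#' @export
significantCells <- function(x) {
  stopifnot(is(x, "LogoMatrix"))
  if (!length(x@heights)) stop("heights not computed; run logoHeights() first")
  h <- x@heights
  idx <- which(abs(h) > x@bonferroni, arr.ind = TRUE)
  out <- data.frame(position = as.integer(colnames(h)[idx[, 2L]]),
                    residue = rownames(h)[idx[, 1L]],
                    height = h[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$height), out$position, out$residue), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified probability-logo comparison
#'
#' Runs the full logo analysis for several window strata (e.g. secretory Ser
#' vs secretory Thr vs cytosolic Ser) against one shared background, so
#' heights are directly comparable across strata.
#'
#' @param siteSets Named list of window vectors (or data.frames with a
#'   `window` column), one per stratum.
#' @param background Background windows or frequency vector.
#' @param alpha Family-wise error rate per logo.
#' @return Named list of [LogoMatrix-class], one per stratum.
#' @export
stratifiedCompare <- function(siteSets, background, alpha = 0.05) {
  if (length(siteSets) == 0L) stop("need at least one stratum")
  if (is.null(names(siteSets)) || any(!nzchar(names(siteSets))))
    stop("strata must be named")
  bg <- backgroundFrequencies(background)
  lapply(siteSets, function(w) logoHeights(countMatrix(w), bg, alpha = alpha))
}

#' Write a LogoMatrix to TSV files plus a JSON summary
#'
#' One TSV each for counts, frequencies and heights (rows = residues, columns
#' = signed offsets) and a JSON summary holding `n_windows`, the Bonferroni
#' threshold and the significant cells.
#'
#' @param x A [LogoMatrix-class] with heights computed.
#' @param prefix Output path prefix; files `<prefix>_counts.tsv`,
#'   `_freqs.tsv`, `_heights.tsv`, `_summary.json` are written.
#' @return Invisibly, the paths written.
#' @export
writeLogoMatrix <- function(x, prefix) {
  paths <- paste0(prefix, c("_counts.tsv", "_freqs.tsv", "_heights.tsv",
                            "_summary.json"))
  for (i in 1:3) {
    m <- list(x@counts, x@freqs, x@heights)[[i]]
    df <- data.frame(residue = rownames(m), m, check.names = FALSE)
    write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_windows = x@nWindows,
         bonferroni_threshold = x@bonferroni,
         center_composition = as.list(x@centerComposition),
         significant_cells = significantCells(x)),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
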