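#' Plot a probability-logo height profile
#'
#' A simple stacked-letter rendering for inspection: at each offset, letters
#' are drawn with vertical extent proportional to their signed height (over-
#' represented above the axis, under-represented below), with the Bonferroni
#' threshold drawn as horizontal lines. The TSV matrices are the contract;
#' this plot is a convenience.
#'
#' @param x A [LogoMatrix-class] with heights computed.
#' @param maxLetters Letters drawn per offset and direction, default 4.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotLogoMatrix <- function(x, maxLetters = 4L, ...) {
  stopifnot(is(x, "LogoMatrix"))
  h <- x@heights
  offs <- as.integer(colnames(h))
  ylim <- range(c(h, x@bonferroni, -x@bonferroni)) * 1.1
  graphics::plot(NA, xlim = range(offs) + c(-0.5, 0.5), ylim = ylim,
                 xlab = "offset from phosphosite",
                 ylab = "signed -log10 binomial tail", ...)
  graphics::abline(h = c(-x@bonferroni, 0, x@bonferroni),
                   lty = c(2, 1, 2), col = c("red", "black", "red"))
  for (j in seq_along(offs)) {
    up <- sort(h[h[, j] > 0, j], decreasing = TRUE)
    dn <- sort(h[h[, j] < 0, j])
    y <- 0
    for (r in names(utils::head(up, maxLetters))) {
      graphics::text(offs[j], y + up[r] / 2, r, cex = 0.7)
      y <- y + up[r]
    }
    y <- 0
    for (r in names(utils::head(dn, maxLetters))) {
      graphics::text(offs[j], y + dn[r] / 2, r, cex = 0.7, col = "grey40")
      y <- y + dn[r]
    }
  }
  invisible(NULL)
}

#' Plot a kinase glutamate-preference heatmap
#'
#' Base-graphics heatmap of a [PreferenceMatrix-class]: rows are kinases,
#' columns positions, shading the normalized glutamate preference.
#'
#' @param x A [PreferenceMatrix-class].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plotPreferenceMatrix <- function(x, ...) {
  stopifnot(is(x, "PreferenceMatrix"))
  v <- x@values
  graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)), z = t(v),
                  zlim = c(0, 1), col = grDevices::hcl.colors(64, "YlOrRd",
                                                              rev = TRUE),
                  axes = FALSE, xlab = "offset from phosphosite",
                  ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(v)), labels = colnames(v))
  graphics::axis(2, at = seq_len(nrow(v)), labels = rownames(v), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(NULL)
}
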