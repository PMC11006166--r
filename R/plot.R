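#' Coefficient and confidence-interval plot
#'
#' Horizontal point-and-bar display of a fitted coefficient table: terms on
#' the vertical axis (intercept at the top, then effects and interactions
#' by order), estimates as points and 95% confidence intervals as bars,
#' with alternating background shading separating interaction orders.
#' Terms whose Holm-adjusted p-value falls below 0.05 are drawn in red.
#'
#' @param x An `"avg_coef_table"` from [fit_fixed()] or [fit_mixed()].
#' @param main Plot title.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.avg_coef_table <- function(x, main = NULL, ...) {
  k <- nrow(x)
  ypos <- rev(seq_len(k))
  has_ci <- all(is.finite(x$ci_low))
  xlim <- if (has_ci) range(x$ci_low, x$ci_high, 0) else range(x$estimate, 0)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "estimate (phenotype units)", ylab = "",
                 main = main %||% "model coefficients", ...)
  for (o in unique(x$order)) {
    if (o %% 2L == 1L) {
      idx <- ypos[x$order == o]
      graphics::rect(graphics::par("usr")[1], min(idx) - 0.5,
                     graphics::par("usr")[2], max(idx) + 0.5,
                     col = "grey92", border = NA)
    }
  }
  graphics::abline(v = 0, lty = 2, col = "grey50")
  sig <- !is.na(x$p_holm) & x$p_holm < 0.05
  col <- ifelse(sig, "red3", "grey20")
  if (has_ci) {
    graphics::segments(x$ci_low, ypos, x$ci_high, ypos, col = col, lwd = 2)
  }
  graphics::points(x$estimate, ypos, pch = 19, col = col)
  graphics::axis(2, at = ypos, labels = x$term, las = 1, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
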