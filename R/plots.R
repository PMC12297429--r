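#' Plot replicate CV against concentration with the LOQ threshold
#'
#' Shows the per-level CVs, the selected polynomial fit, the CV threshold as
#' a dashed horizontal line, and the LOQ as a dashed vertical line when
#' defined.
#'
#' @param result a `sensitivity_result` from [estimate_loq()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_cv_curve <- function(result, ...) {
  stopifnot(inherits(result, "sensitivity_result"))
  lv <- result$cv_by_level
  x <- log10(lv$mean_conc_reaction)
  graphics::plot(x, lv$cv, xlab = "log10 concentration (copies/uL reaction)",
                 ylab = "replicate CV", pch = 19,
                 ylim = range(0, lv$cv, result$cv_threshold * 1.2), ...)
  grid_x <- seq(min(x), max(x), length.out = 200)
  coefs <- result$model_table$coefficients[[
    which(result$model_table$degree == result$selected_degree)]]
  graphics::lines(grid_x, predict_poly(coefs, grid_x), col = "steelblue")
  graphics::abline(h = result$cv_threshold, lty = 2)
  if (result$loq_defined) graphics::abline(v = log10(result$loq), lty = 2,
                                           col = "firebrick")
  invisible(result)
}

#' Bland-Altman plot
#'
#' Pair means against differences, with bias and limits of agreement drawn
#' as horizontal lines.
#'
#' @param ba a `ba_result` from [bland_altman()].
#' @param pairs the [paired_measurements()] the result was computed from.
#' @param ... passed to [graphics::plot()].
#' @export
plot_bland_altman <- function(ba, pairs, ...) {
  stopifnot(inherits(ba, "ba_result"), inherits(pairs, "paired_measurements"))
  d <- pairs$x - pairs$y
  m <- (pairs$x + pairs$y) / 2
  graphics::plot(m, d, xlab = "pair mean", ylab = paste("difference",
                                                        ba$orientation),
                 pch = 19, ...)
  graphics::abline(h = ba$bias, col = "steelblue")
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2, col = "firebrick")
  invisible(ba)
}
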