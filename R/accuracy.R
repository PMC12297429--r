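#' Expected copy number from a DNA mass
#'
#' Converts a mass of a DNA fragment into an absolute number of molecules:
#' `mass_ng * avogadro / (mw_g_per_mol * ng_per_g)`. With the mass in ng/uL
#' the result is copies/uL of template. The default molecular weight is that
#' of the 237 bp rRNA-gene amplicon the package's default scenarios emulate.
#'
#' @param mass_ng amount of fragment in ng (or ng/uL for a concentration).
#' @param mw_g_per_mol molecular weight of the fragment (default 146,288.9
#'   g/mol).
#' @param avogadro Avogadro's constant (default 6.0221e23 molecules/mol).
#' @return Expected number of copies (per uL if `mass_ng` was per uL).
#' @export
#' @examples
#' expected_copies(1.68)  # ~6.916e9 copies/uL for the measured stock
expected_copies <- function(mass_ng, mw_g_per_mol = 146288.9,
                            avogadro = 6.0221e23) {
  if (any(!is.finite(mass_ng)) || any(mass_ng < 0))
    stop_input("mass_ng must be finite and >= 0")
  if (!is.finite(mw_g_per_mol) || mw_g_per_mol <= 0 ||
      !is.finite(avogadro) || avogadro <= 0)
    stop_input("mw_g_per_mol and avogadro must be positive")
  mass_ng * avogadro / (mw_g_per_mol * 1e9)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, the precision measure used
#' throughout the package (replicate agreement, LOQ threshold).
#'
#' @param x at least two finite values with nonzero mean.
#' @return CV as a fraction (0.10 means 10%).
#' @export
#' @examples
#' cv(c(90, 100, 110))  # 0.10
cv <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L || any(!is.finite(x)))
    stop_input("cv needs at least 2 finite values")
  m <- mean(x)
  if (m == 0) stop_input("cv undefined for zero mean")
  stats::sd(x) / m
}

#' Replicate precision by technical or biological level
#'
#' Technical precision is the CV across technical replicates within one
#' extract (one `sample_id`). Biological precision takes the mean of each
#' biological replicate's technical replicates as the unit of analysis and
#' computes the CV of those means across biological replicates of the same
#' condition (cell number, or dilution level).
#'
#' @param conc a quantified `concentration_table`.
#' @param level `"technical"` or `"biological"`.
#' @param value column to summarize (default `"conc_reaction"`).
#' @return A data.frame with the grouping labels, `n` and `cv`.
#' @export
replicate_cv <- function(conc, level = c("technical", "biological"),
                         value = "conc_reaction") {
  level <- match.arg(level)
  ok <- conc$status == "ok"
  conc <- conc[ok, , drop = FALSE]
  if (nrow(conc) == 0L) stop_input("no quantified wells")
  key <- if (!all(is.na(conc$cell_number))) "cell_number" else "dilution_level"
  if (level == "technical") {
    sp <- split(conc, list(conc[[key]], conc$replicate_bio, conc$enzyme,
                           conc$platform), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(g) data.frame(
      group = g[[key]][1L], replicate_bio = g$replicate_bio[1L],
      enzyme = g$enzyme[1L], platform = g$platform[1L], n = nrow(g),
      cv = if (nrow(g) >= 2L) cv(g[[value]]) else NA_real_)))
  } else {
    sp <- split(conc, list(conc[[key]], conc$enzyme, conc$platform),
                drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(g) {
      bio_means <- tapply(g[[value]], g$replicate_bio, mean)
      data.frame(group = g[[key]][1L], enzyme = g$enzyme[1L],
                 platform = g$platform[1L], n = length(bio_means),
                 cv = if (length(bio_means) >= 2L) cv(bio_means) else NA_real_)
    }))
  }
  rownames(out) <- NULL
  names(out)[names(out) == "group"] <- key
  out
}

#' Accuracy of measured against analytically expected concentrations
#'
#' Compares measured concentrations with expected ones on the log10-log10
#' scale: polynomial regressions of degree 1 to `max_degree` are fitted and
#' the minimum-AIC model selected (ties to the lower degree). Per expected
#' level the mean measurement, measured/expected ratio and replicate CV are
#' reported.
#'
#' @param expected expected concentrations (positive, one per measurement).
#' @param measured measured concentrations (positive, same length).
#' @param max_degree highest polynomial degree to try (default 3).
#' @return A list of class `accuracy_report` with `per_level` and `regression`
#'   (`degree`, `coefficients`, `adjusted_r2`, `aic`, `model_table`).
#' @export
#' @examples
#' accuracy_regression(rep(10^(1:5), each = 2),
#'                     rep(10^(1:5), each = 2) * 0.5)
accuracy_regression <- function(expected, measured, max_degree = 3L) {
  if (length(expected) != length(measured))
    stop_input("expected and measured must have equal length")
  if (any(!is.finite(expected)) || any(!is.finite(measured)) ||
      any(expected <= 0) || any(measured <= 0))
    stop_input("expected and measured must be positive and finite")
  if (length(unique(expected)) < max_degree + 2L)
    stop_input("need at least ", max_degree + 2L, " distinct expected levels")
  lx <- log10(expected); ly <- log10(measured)
  sel <- select_poly_aic(lx, ly, max_degree)
  sp <- split(data.frame(expected, measured), expected)
  per_level <- do.call(rbind, lapply(sp, function(g) data.frame(
    expected = g$expected[1L],
    measured_mean = mean(g$measured),
    ratio = mean(g$measured) / g$expected[1L],
    cv = if (nrow(g) >= 2L) cv(g$measured) else NA_real_)))
  per_level <- per_level[order(per_level$expected), , drop = FALSE]
  rownames(per_level) <- NULL
  best <- sel$model_table[sel$model_table$degree == sel$selected_degree, ]
  structure(list(
    per_level = per_level,
    regression = list(degree = sel$selected_degree,
                      coefficients = best$coefficients[[1L]],
                      adjusted_r2 = best$adj_r2, aic = best$aic,
                      model_table = sel$model_table[, c("degree", "aic",
                                                        "adj_r2")])),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  cat(sprintf("  regression: degree %d, adjusted R^2 = %.4f\n",
              x$regression$degree, x$regression$adjusted_r2))
  cat(sprintf("  ratio measured/expected: %.3g to %.3g over %d levels\n",
              min(x$per_level$ratio), max(x$per_level$ratio),
              nrow(x$per_level)))
  invisible(x)
}
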