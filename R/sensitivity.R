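#' Assemble a dilution series from quantified wells
#'
#' Groups a quantified well table (from [quantify_well()]) by dilution level
#' and collects, per level, the replicate concentration estimates and the
#' detection / saturation tallies used by [estimate_lod()] and
#' [estimate_loq()]. Levels are ordered by decreasing dilution (increasing
#' nominal concentration is not required on input; the output is sorted).
#'
#' @param conc a `concentration_table` with `dilution_level` and
#'   `nominal_conc` populated.
#' @return A list of class `dilution_series` with elements `levels` (a
#'   data.frame with `dilution_level`, `nominal_conc`, `mean_conc_reaction`,
#'   `n_replicates`, `n_detected`, `n_saturated`, `cv`, and a list-column
#'   `estimates` of per-replicate `conc_reaction` values) and
#'   `excluded_levels` (empty until [filter_dynamic_range()] runs).
#' @export
build_dilution_series <- function(conc) {
  if (!all(c("dilution_level", "nominal_conc", "conc_reaction", "status")
           %in% names(conc)))
    stop_input("input must be a quantified concentration table")
  conc <- conc[!is.na(conc$dilution_level), , drop = FALSE]
  if (nrow(conc) == 0L) stop_input("no dilution-series wells in input")
  sp <- split(conc, conc$dilution_level)
  lev <- do.call(rbind, lapply(sp, function(g) {
    ok <- g$status == "ok"
    data.frame(
      dilution_level = g$dilution_level[1L],
      nominal_conc = g$nominal_conc[1L],
      nominal_conc_reaction = g$nominal_conc[1L] * g$template_volume_uL[1L] /
        g$reaction_volume_uL[1L],
      mean_conc_reaction = if (any(ok)) mean(g$conc_reaction[ok]) else NA_real_,
      n_replicates = nrow(g),
      n_detected = sum(g$status != "below_detection"),
      n_saturated = sum(g$status == "oversaturated"),
      cv = if (sum(ok) >= 2L && mean(g$conc_reaction[ok]) > 0)
        stats::sd(g$conc_reaction[ok]) / mean(g$conc_reaction[ok])
      else NA_real_)
  }))
  lev$estimates <- I(lapply(sp, function(g)
    g$conc_reaction[g$status == "ok"]))
  lev <- lev[order(lev$nominal_conc), , drop = FALSE]
  rownames(lev) <- NULL
  structure(list(levels = lev,
                 excluded_levels = data.frame(dilution_level = integer(),
                                              nominal_conc = double(),
                                              reason = character())),
            class = "dilution_series")
}

#' Restrict a dilution series to its interpretable dynamic range
#'
#' High concentrations oversaturate a dPCR platform (every partition positive,
#' Poisson estimate undefined) and very low concentrations give no signal
#' distinguishable from background; both ends must be excluded before
#' sensitivity estimation. A level is dropped as `oversaturated` when at
#' least half of its replicates are saturated, and as `weak_signal` when no
#' replicate detected the target. Exclusions are recorded on the returned
#' object.
#'
#' @param series a `dilution_series`.
#' @return The filtered `dilution_series` with `excluded_levels` populated.
#' @export
filter_dynamic_range <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  lev <- series$levels
  if (nrow(lev) == 0L) stop_input("empty dilution series")
  sat <- lev$n_saturated >= lev$n_replicates / 2
  weak <- !sat & lev$n_detected == 0L
  drop <- sat | weak
  if (all(drop))
    stop_input("all dilution levels excluded: no interpretable dynamic range")
  excl <- data.frame(dilution_level = lev$dilution_level[drop],
                     nominal_conc = lev$nominal_conc[drop],
                     reason = ifelse(sat[drop], "oversaturated", "weak_signal"))
  series$excluded_levels <- rbind(series$excluded_levels, excl)
  series$levels <- lev[!drop, , drop = FALSE]
  series
}

#' Limit of detection from replicate detection fractions
#'
#' The LOD is defined as the lowest concentration at which the assay detects
#' the target in `detect_prob` (default 95%) of replicates. A binomial GLM of
#' the per-level detection fraction on log10 concentration (logit link by
#' default, probit available) is fitted and inverted at `detect_prob`. When
#' every level is fully detected down to the lowest tested concentration the
#' LOD cannot be interior; the lowest tested concentration is returned and
#' flagged as an upper bound. Confidence intervals come from a per-level
#' binomial bootstrap of the detection counts at their empirical fractions.
#'
#' @param series a `dilution_series` (ideally after [filter_dynamic_range()];
#'   weak-signal levels carry detection information and are used if present).
#' @param detect_prob target detection probability (default 0.95).
#' @param link `"logit"` or `"probit"`.
#' @param n_boot bootstrap replicates for the CI.
#' @param seed integer seed for the bootstrap.
#' @param conf_level CI level.
#' @return A list with `lod` (copies/uL of reaction mix), `ci_low`, `ci_high`,
#'   `upper_bound_flag`, `link`, `coefficients` and `n_boot_ok`.
#' @export
estimate_lod <- function(series, detect_prob = 0.95, link = "logit",
                         n_boot = 500L, seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(series, "dilution_series"))
  if (detect_prob <= 0 || detect_prob >= 1)
    stop_input("detect_prob must be in (0,1)")
  lev <- series$levels
  # weak-signal exclusions are informative zeros for the detection curve
  keep <- (is.finite(lev$nominal_conc) & lev$nominal_conc > 0) |
    is.finite(lev$mean_conc_reaction)
  lev <- lev[keep, , drop = FALSE]
  if (nrow(lev) < 2L) stop_input("need at least 2 levels to estimate LOD")
  # known input concentration on the reaction scale: the measured mean over
  # detected replicates is selection-biased exactly where the LOD lives
  conc <- lev$nominal_conc_reaction
  if (is.null(conc)) conc <- lev$nominal_conc
  bad <- !is.finite(conc) | conc <= 0
  conc[bad] <- lev$mean_conc_reaction[bad]
  x <- log10(conc)
  det <- lev$n_detected
  n <- lev$n_replicates
  if (all(det == n)) {
    return(list(lod = min(conc), ci_low = NA_real_, ci_high = min(conc),
                upper_bound_flag = TRUE, link = link,
                coefficients = NULL, n_boot_ok = 0L))
  }
  fit_lod <- function(det_i) {
    fit <- suppressWarnings(
      stats::glm(cbind(det_i, n - det_i) ~ x,
                 family = stats::binomial(link = link)))
    b <- stats::coef(fit)
    if (!all(is.finite(b)) || b[2L] <= 0) return(NA_real_)
    q <- switch(link, logit = stats::qlogis(detect_prob),
                probit = stats::qnorm(detect_prob))
    10^((q - b[1L]) / b[2L])
  }
  lod <- fit_lod(det)
  if (!is.finite(lod))
    stop_input("LOD estimation failed: detection fraction not increasing in ",
               "concentration (levels: ", paste(round(det / n, 2),
                                                collapse = ", "), ")")
  # parametric bootstrap from the fitted curve: resampling raw per-level
  # fractions is anti-conservative at 10 replicates/level (granular p-hat)
  fit0 <- suppressWarnings(stats::glm(cbind(det, n - det) ~ x,
                                      family = stats::binomial(link = link)))
  p_fit <- stats::fitted(fit0)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      fit_lod(stats::rbinom(length(n), n, p_fit))
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  a <- (1 - conf_level) / 2
  ci <- if (length(boot) >= 10L)
    stats::quantile(boot, c(a, 1 - a), names = FALSE) else c(NA_real_, NA_real_)
  list(lod = unname(lod), ci_low = ci[1L], ci_high = ci[2L],
       upper_bound_flag = FALSE, link = link,
       coefficients = unname(stats::coef(fit0)), n_boot_ok = length(boot))
}

#' Limit of quantification from replicate coefficients of variation
#'
#' The LOQ is the lowest concentration at which technical replicates achieve a
#' coefficient of variation at or below `cv_threshold` (default 0.35).
#' Per-level CVs (sample sd / mean of the replicate `conc_reaction`
#' estimates) are modeled as polynomial functions of log10 concentration for
#' degrees 1 to `max_degree`; the minimum-AIC model is selected (Gaussian
#' likelihood, ties broken toward the lower degree). The LOQ is the lowest
#' point of a 1000-point log-spaced grid across the retained range where the
#' fitted curve is at or below the threshold. The lowest observed level whose
#' raw CV meets the threshold is also reported (`loq_empirical`).
#'
#' @param series a `dilution_series`, normally after [filter_dynamic_range()].
#' @param cv_threshold maximum acceptable CV (fraction, in (0,1)).
#' @param max_degree highest polynomial degree to try (default 3).
#' @param grid_points size of the log-spaced search grid.
#' @return A list of class `sensitivity_result` with `loq`, `loq_defined`,
#'   `loq_empirical`, `cv_threshold`, `model_table`, `selected_degree`,
#'   `cv_by_level` and the search `grid_range`.
#' @export
estimate_loq <- function(series, cv_threshold = 0.35, max_degree = 3L,
                         grid_points = 1000L) {
  stopifnot(inherits(series, "dilution_series"))
  if (cv_threshold <= 0 || cv_threshold >= 1)
    stop_input("cv_threshold must be in (0,1)")
  lev <- series$levels
  usable <- !is.na(lev$cv) & is.finite(lev$mean_conc_reaction) &
    lev$mean_conc_reaction > 0
  lev <- lev[usable, , drop = FALSE]
  if (nrow(lev) < max_degree + 2L)
    stop_input("need at least ", max_degree + 2L,
               " levels with >= 2 quantified replicates (have ", nrow(lev), ")")
  x <- log10(lev$mean_conc_reaction)
  sel <- select_poly_aic(x, lev$cv, max_degree)
  grid <- seq(min(x), max(x), length.out = grid_points)
  coefs <- sel$model_table$coefficients[[
    which(sel$model_table$degree == sel$selected_degree)]]
  fitted_cv <- predict_poly(coefs, grid)
  below <- which(fitted_cv <= cv_threshold)
  loq <- if (length(below)) 10^grid[min(below)] else NA_real_
  emp <- which(lev$cv <= cv_threshold)
  structure(list(
    loq = loq, loq_defined = length(below) > 0,
    loq_empirical = if (length(emp)) lev$mean_conc_reaction[min(emp)]
    else NA_real_,
    cv_threshold = cv_threshold,
    model_table = sel$model_table[, c("degree", "aic", "adj_r2",
                                      "coefficients")],
    selected_degree = sel$selected_degree,
    cv_by_level = lev[, c("dilution_level", "nominal_conc",
                          "mean_conc_reaction", "cv")],
    grid_range = range(10^grid)),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>\n")
  cat(sprintf("  LOQ (fitted crossing): %s copies/uL reaction (CV <= %.2f)\n",
              if (x$loq_defined) format(signif(x$loq, 4)) else "undefined",
              x$cv_threshold))
  cat(sprintf("  LOQ (lowest raw CV <= threshold): %s\n",
              format(signif(x$loq_empirical, 4))))
  cat(sprintf("  selected model: degree %d (min AIC of %s)\n",
              x$selected_degree,
              paste(x$model_table$degree, collapse = ",")))
  invisible(x)
}
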