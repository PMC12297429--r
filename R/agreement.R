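#' Paired cross-platform measurements
#'
#' Holds aligned concentration measurements from two platforms. By package
#' convention `x` is the nanoplate measurement and `y` the droplet
#' measurement, and all differences are `x - y` (nanoplate minus droplet);
#' this orientation is recorded in every result.
#'
#' @param x,y equal-length (>= 3) measurement vectors.
#' @param group optional per-pair label (dilution level or cell number) used
#'   for inverse-variance weighting.
#' @param log_transform if `TRUE`, both axes are log10-transformed (requires
#'   positive values).
#' @param labels platform names for `x` and `y`.
#' @return A list of class `paired_measurements`.
#' @export
paired_measurements <- function(x, y, group = NULL, log_transform = FALSE,
                                labels = c("nanoplate", "droplet")) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("x and y must be finite")
  if (log_transform) {
    if (any(x <= 0) || any(y <= 0))
      stop_input("log transform requires positive values")
    x <- log10(x); y <- log10(y)
  }
  if (!is.null(group) && length(group) != length(x))
    stop_input("group must match the number of pairs")
  structure(list(x = x, y = y, group = group,
                 log_transformed = log_transform, labels = labels),
            class = "paired_measurements")
}

ccc_point <- function(x, y, moments = "population") {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  if (moments == "population") {
    sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
    sxy <- mean((x - mx) * (y - my))
  } else {
    sx2 <- stats::var(x); sy2 <- stats::var(y)
    sxy <- stats::cov(x, y)
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Lin's concordance correlation coefficient with bootstrap CI
#'
#' CCC combines precision (Pearson correlation) with accuracy (closeness to
#' the identity line):
#' `CCC = 2 * rho * sx * sy / (sx^2 + sy^2 + (mx - my)^2)`.
#' Moments default to the population (1/n) form of the standard definition; a
#' sample-moment variant is available. The CI is a seeded percentile
#' bootstrap over pair-level resampling.
#'
#' @param pairs a [paired_measurements()].
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf_level CI level (default 0.95).
#' @param moments `"population"` or `"sample"`.
#' @return A list with `ccc`, `ci_low`, `ci_high`, `pearson_rho`, the moments
#'   used, and `n`.
#' @export
#' @examples
#' p <- paired_measurements(1:10, (1:10) + 2)
#' ccc(p, n_boot = 200, seed = 1)$ccc  # < 1: shifted but correlated
ccc <- function(pairs, n_boot = 2000L, seed = 1L, conf_level = 0.95,
                moments = c("population", "sample")) {
  stopifnot(inherits(pairs, "paired_measurements"))
  moments <- match.arg(moments)
  x <- pairs$x; y <- pairs$y
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_input("ccc undefined: zero variance on one axis")
  est <- ccc_point(x, y, moments)
  n <- length(x)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    ccc_point(x[idx], y[idx], moments)
  }, numeric(1)))
  boot <- boot[is.finite(boot)]
  a <- (1 - conf_level) / 2
  ci <- if (length(boot) >= 10L)
    stats::quantile(boot, c(a, 1 - a), names = FALSE) else c(NA_real_, NA_real_)
  list(ccc = est, ci_low = ci[1L], ci_high = ci[2L],
       pearson_rho = stats::cor(x, y), moments = moments, n = n)
}

#' Bland-Altman agreement analysis, classic or inverse-variance weighted
#'
#' Differences are `d = x - y` (nanoplate minus droplet). The classic
#' analysis reports `bias = mean(d)` with limits of agreement
#' `bias +/- 1.96 sd(d)`. The weighted analysis assigns each pair
#' `w_i = 1 / sigma_i^2`, where `sigma_i^2` is the variance of the
#' differences within the pair's group (dilution level or cell number);
#' groups with fewer than 2 pairs receive the pooled within-group variance.
#' The weighted bias is `sum(w_i d_i) / sum(w_i)` and the weighted limits use
#' the weighted standard deviation analogously. Proportional bias is the
#' slope of `d` on the pair means.
#'
#' @param pairs a [paired_measurements()]; for `weighted = TRUE` it must carry
#'   a `group` with at least one group of >= 2 pairs.
#' @param weighted use inverse-variance weighting (default `FALSE`).
#' @return A list of class `ba_result`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `prop_bias_beta1`, `prop_bias_p`, `prop_bias_se`, `weights`
#'   (NULL when classic), `weighted`, `orientation`, `n`.
#' @export
#' @examples
#' p <- paired_measurements(c(10, 20, 30, 40), c(9, 18, 29, 41))
#' bland_altman(p)$bias
bland_altman <- function(pairs, weighted = FALSE) {
  stopifnot(inherits(pairs, "paired_measurements"))
  d <- pairs$x - pairs$y
  m <- (pairs$x + pairs$y) / 2
  n <- length(d)
  w <- NULL
  if (weighted) {
    if (is.null(pairs$group))
      stop_input("weighted Bland-Altman needs a per-pair group")
    g <- split(d, pairs$group)
    sizes <- lengths(g)
    if (!any(sizes >= 2L))
      stop_input("weighted Bland-Altman needs at least one group with >= 2 pairs")
    vars <- vapply(g, function(di)
      if (length(di) >= 2L) stats::var(di) else NA_real_, numeric(1))
    dfree <- sizes - 1L
    pooled <- sum(vars * dfree, na.rm = TRUE) / sum(dfree[!is.na(vars)])
    vars[is.na(vars) | vars == 0] <- if (pooled > 0) pooled else
      stop_input("all within-group variances are zero; weights undefined")
    w <- (1 / vars)[match(as.character(pairs$group), names(vars))]
    bias <- sum(w * d) / sum(w)
    sd_d <- sqrt(sum(w * (d - bias)^2) / sum(w))
  } else {
    bias <- mean(d)
    sd_d <- stats::sd(d)
  }
  fit <- stats::lm(d ~ m)
  # constant differences are a valid degenerate case; summary.lm warns on them
  sm <- suppressWarnings(summary(fit)$coefficients)
  beta1 <- if (nrow(sm) > 1L) sm[2L, 1L] else 0
  beta1_se <- if (nrow(sm) > 1L) sm[2L, 2L] else NA_real_
  beta1_p <- if (nrow(sm) > 1L) sm[2L, 4L] else NA_real_
  structure(list(bias = bias, loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d, sd_diff = sd_d,
                 prop_bias_beta1 = unname(beta1),
                 prop_bias_se = unname(beta1_se),
                 prop_bias_p = unname(beta1_p),
                 weights = w, weighted = weighted,
                 orientation = paste(pairs$labels, collapse = " - "),
                 log_transformed = pairs$log_transformed, n = n),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("<ba_result> %s (%s)\n", x$orientation,
              if (x$weighted) "inverse-variance weighted" else "classic"))
  cat(sprintf("  bias %.4g [LoA %.4g, %.4g], prop. bias b1 = %.4g (p = %.3g)\n",
              x$bias, x$loa_low, x$loa_high, x$prop_bias_beta1, x$prop_bias_p))
  invisible(x)
}

#' Paired difference test with assumption-based selection
#'
#' Tests whether the two platforms differ on average. A Shapiro-Wilk test on
#' the paired differences decides the test: approximately normal differences
#' (p > `alpha`) get a paired Student's t-test, otherwise a Wilcoxon
#' signed-rank test. If every difference is zero, a no-difference record is
#' returned without testing.
#'
#' @param pairs a [paired_measurements()].
#' @param alpha normality-decision level (default 0.05).
#' @return A list with `name` (`"paired_t"`, `"wilcoxon"` or
#'   `"no_difference"`), `statistic`, `p_value`, `shapiro_p`.
#' @export
paired_test <- function(pairs, alpha = 0.05) {
  stopifnot(inherits(pairs, "paired_measurements"))
  d <- pairs$x - pairs$y
  if (all(d == 0))
    return(list(name = "no_difference", statistic = NA_real_, p_value = 1,
                shapiro_p = NA_real_))
  sw <- stats::shapiro.test(d)
  if (sw$p.value > alpha) {
    tt <- stats::t.test(pairs$x, pairs$y, paired = TRUE)
    list(name = "paired_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, shapiro_p = sw$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(pairs$x, pairs$y, paired = TRUE,
                                              exact = FALSE))
    list(name = "wilcoxon", statistic = unname(wt$statistic),
         p_value = wt$p.value, shapiro_p = sw$p.value)
  }
}

#' Heteroscedasticity check on paired differences
#'
#' Regresses the absolute differences `|d|` on the pair means; a
#' significantly positive slope (at `alpha`) flags variability growing with
#' magnitude. The decision rule the pipeline applies: log-transform first,
#' and if the log-scale differences are still flagged, use the weighted
#' Bland-Altman analysis.
#'
#' @param pairs a [paired_measurements()] with >= 6 pairs.
#' @param alpha significance level (default 0.05).
#' @return A list with `heteroscedastic` flag, `slope`, `p_value`.
#' @export
heteroscedasticity_check <- function(pairs, alpha = 0.05) {
  stopifnot(inherits(pairs, "paired_measurements"))
  if (length(pairs$x) < 6L) stop_input("need at least 6 pairs")
  d <- abs(pairs$x - pairs$y)
  m <- (pairs$x + pairs$y) / 2
  if (stats::sd(d) == 0 || stats::sd(m) == 0)
    return(list(heteroscedastic = FALSE, slope = 0, p_value = 1))
  sm <- summary(stats::lm(d ~ m))$coefficients
  slope <- sm[2L, 1L]; p <- sm[2L, 4L]
  list(heteroscedastic = slope > 0 && p < alpha,
       slope = unname(slope), p_value = unname(p))
}

#' Full cross-platform agreement analysis
#'
#' Convenience wrapper running the whole agreement stage on one pair of
#' aligned measurement vectors: paired test, CCC with bootstrap CI,
#' heteroscedasticity-driven choice between classic and weighted
#' Bland-Altman (log10 scale throughout, following the decision rule in
#' [heteroscedasticity_check()]).
#'
#' @param x,y positive aligned concentration vectors (nanoplate, droplet).
#' @param group per-pair group label for weighting.
#' @param n_boot,seed,conf_level,alpha passed to the component analyses.
#' @return A list of class `agreement_result` with `ccc`, `bland_altman`
#'   (the analysis chosen by the decision rule), `bland_altman_classic`,
#'   `test`, `heteroscedasticity`, `pairs`.
#' @export
compare_platforms <- function(x, y, group = NULL, n_boot = 2000L, seed = 1L,
                              conf_level = 0.95, alpha = 0.05) {
  plog <- paired_measurements(x, y, group = group, log_transform = TRUE)
  het <- if (length(x) >= 6L) heteroscedasticity_check(plog, alpha)
  else list(heteroscedastic = FALSE, slope = NA_real_, p_value = NA_real_)
  ccc_res <- ccc(plog, n_boot = n_boot, seed = seed, conf_level = conf_level)
  ba_classic <- bland_altman(plog, weighted = FALSE)
  ba <- if (het$heteroscedastic && !is.null(group))
    bland_altman(plog, weighted = TRUE) else ba_classic
  structure(list(ccc = ccc_res, bland_altman = ba,
                 bland_altman_classic = ba_classic,
                 test = paired_test(plog, alpha),
                 heteroscedasticity = het, pairs = plog),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result>\n")
  cat(sprintf("  CCC = %.4f [%.4f, %.4f] (rho = %.4f, n = %d)\n",
              x$ccc$ccc, x$ccc$ci_low, x$ccc$ci_high, x$ccc$pearson_rho,
              x$ccc$n))
  cat(sprintf("  %s test: p = %.3g\n", x$test$name, x$test$p_value))
  print(x$bland_altman)
  invisible(x)
}
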