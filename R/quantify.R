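#' Poisson estimate of mean copies per partition
#'
#' In digital PCR the template is randomly distributed over partitions, so the
#' number of copies per partition is Poisson. The fraction of negative
#' partitions estimates `exp(-lambda)`, giving the standard estimator
#' `lambda = -log(n_neg / n_total)`.
#'
#' @param n_total number of analyzable partitions (>= 1).
#' @param n_positive number of positive partitions, `0 <= n_positive <
#'   n_total` (a fully positive well is oversaturated and carries no finite
#'   estimate; see [quantify_well()] which flags it instead of erroring).
#' @return Mean copies per partition (dimensionless, >= 0).
#' @export
#' @examples
#' estimate_lambda(20000, 10000)  # log(2)
estimate_lambda <- function(n_total, n_positive) {
  assert_scalar_num(n_total, "n_total", 1, strict = FALSE)
  assert_scalar_num(n_positive, "n_positive", 0)
  if (n_positive > n_total) stop_input("n_positive exceeds n_total")
  if (n_positive == n_total)
    stop_input("all ", n_total,
               " partitions positive: well is oversaturated, lambda undefined")
  -log((n_total - n_positive) / n_total)
}

# Wilson score interval on a binomial proportion
wilson_interval <- function(k, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Quantify a well: from partition counts to concentrations
#'
#' Converts partition counts into absolute concentrations. The mean copies per
#' partition `lambda` (from [estimate_lambda()]) divided by the effective
#' partition volume gives copies per uL of reaction mix; multiplying by the
#' reaction volume gives copies per reaction; dividing that by the template
#' input volume gives copies per uL of template DNA. The plate-level
#' `volume_scale` factor rescales the partition volume, mirroring
#' instrument-side volume-precision corrections.
#'
#' Confidence intervals come from a Wilson score interval on the
#' negative-partition fraction propagated through `-log`. Saturated wells
#' (`n_positive == n_total`) and empty wells (`n_positive == 0`) are returned
#' flagged (`status` `"oversaturated"` / `"below_detection"`), never as
#' errors.
#'
#' @param wells a `well_table` (or single-row data.frame with its columns).
#' @param ci_level confidence level for the interval (default 0.95).
#' @return A data.frame with one row per well: the input labels plus
#'   `lambda_hat`, `conc_reaction` (copies/uL reaction), `copies_per_reaction`,
#'   `conc_template` (copies/uL template), `ci_low`, `ci_high` (on
#'   `conc_reaction`) and `status`.
#' @export
#' @examples
#' w <- well_table(n_total = 20000, n_positive = 10000,
#'                 partition_volume_nL = 0.85, reaction_volume_uL = 20)
#' quantify_well(w)$conc_reaction  # ~815.5 copies/uL
quantify_well <- function(wells, ci_level = 0.95) {
  validate_well_table(wells)
  if (ci_level <= 0 || ci_level >= 1) stop_input("ci_level must be in (0,1)")
  n <- nrow(wells)
  out <- as.data.frame(wells)
  out$lambda_hat <- NA_real_
  out$conc_reaction <- NA_real_
  out$copies_per_reaction <- NA_real_
  out$conc_template <- NA_real_
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  out$status <- "ok"
  # effective partition volume in uL, with plate-level scale correction
  v_part <- wells$partition_volume_nL * 1e-3 * wells$volume_scale
  for (i in seq_len(n)) {
    nt <- wells$n_total[i]; np <- wells$n_positive[i]
    if (np == nt) { out$status[i] <- "oversaturated"; next }
    lam <- estimate_lambda(nt, np)
    out$lambda_hat[i] <- lam
    out$conc_reaction[i] <- lam / v_part[i]
    out$copies_per_reaction[i] <- copies_per_reaction(out$conc_reaction[i],
                                                      wells$reaction_volume_uL[i])
    out$conc_template[i] <- out$copies_per_reaction[i] /
      wells$template_volume_uL[i]
    wi <- wilson_interval(nt - np, nt, ci_level)
    out$ci_low[i] <- -log(wi[["high"]]) / v_part[i]
    out$ci_high[i] <- if (wi[["low"]] <= 0) Inf else -log(wi[["low"]]) / v_part[i]
    if (np == 0L) out$status[i] <- "below_detection"
  }
  class(out) <- c("concentration_table", "data.frame")
  out
}

#' Copies per reaction from a concentration
#'
#' Absolute number of target molecules in one reaction: the measured
#' concentration (copies/uL of reaction mix) times the reaction volume (uL).
#'
#' @param conc_reaction concentration in copies/uL of reaction mix (>= 0).
#' @param reaction_volume_uL reaction volume in uL (>= 0).
#' @return Copies per reaction (exact product).
#' @export
#' @examples
#' copies_per_reaction(1.35, 40)  # 54
#' copies_per_reaction(4.26, 20)  # 85.2
copies_per_reaction <- function(conc_reaction, reaction_volume_uL) {
  if (any(!is.finite(conc_reaction)) || any(!is.finite(reaction_volume_uL)) ||
      any(conc_reaction < 0) || any(reaction_volume_uL < 0))
    stop_input("conc_reaction and reaction_volume_uL must be finite and >= 0")
  conc_reaction * reaction_volume_uL
}
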