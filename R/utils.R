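# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("dpcr_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(name, " must be a single finite number")
  if (strict && x <= lower) stop_input(name, " must be > ", lower)
  if (!strict && x < lower) stop_input(name, " must be >= ", lower)
  invisible(x)
}

# lognormal meanlog/sdlog for a multiplicative factor with mean 1 and given CV
lnorm_unit <- function(cv) {
  if (cv <= 0) return(c(meanlog = 0, sdlog = 0))
  s2 <- log(1 + cv^2)
  c(meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# lognormal meanlog/sdlog for given arithmetic mean and CV
lnorm_mean_cv <- function(mean, cv) {
  if (cv <= 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + cv^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# deterministic substream seed per simulation unit; keeps results reproducible
# from one integer and independent of labels that must not perturb draws
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 97 * as.double(index)) %% 2147483647)
}

# fit polynomial regressions of y on x for degrees 1..max_degree and pick the
# minimum-AIC model; ties (dAIC < 1e-9, incl. perfect fits with -Inf AIC) go to
# the lower degree.  Degrees with fewer points than parameters are skipped.
select_poly_aic <- function(x, y, max_degree = 3L) {
  n <- length(x)
  fits <- list()
  tab <- data.frame(degree = integer(), aic = double(), adj_r2 = double())
  for (d in seq_len(max_degree)) {
    if (n < d + 2L) next
    fit <- stats::lm(y ~ stats::poly(x, degree = d, raw = TRUE))
    rss <- sum(stats::residuals(fit)^2)
    aic <- if (rss < n * 1e-24) -Inf else stats::AIC(fit)
    # noise-free inputs are legitimate here; summary.lm warns on them
    adj_r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    tab <- rbind(tab, data.frame(degree = d, aic = aic, adj_r2 = adj_r2))
    fits[[as.character(d)]] <- fit
  }
  if (nrow(tab) == 0L)
    stop_input("not enough points to fit any polynomial degree (n = ", n, ")")
  best <- which(tab$aic <= min(tab$aic) + 1e-9)[1L]
  tab$coefficients <- I(lapply(as.character(tab$degree),
                               function(d) unname(stats::coef(fits[[d]]))))
  list(model_table = tab, selected_degree = tab$degree[best],
       fit = fits[[as.character(tab$degree[best])]],
       adj_r2 = tab$adj_r2[best])
}

predict_poly <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1L, `^`) %*% coefs)
}
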