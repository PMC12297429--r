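# helper: quantified table -> series, for constructed partition-count fixtures
series_from_wells <- function(w) build_dilution_series(quantify_well(w))

test_that("dynamic-range filter drops saturated tops and silent bottoms", {
  # 11 levels: top 4 fully saturated, bottom 1 undetected, 6 interpretable
  mk_level <- function(k, npos) well_table(
    platform = "droplet", dilution_level = k, nominal_conc = 10^(10 - k),
    replicate_tech = 1:4, n_total = 20000L, n_positive = npos,
    reaction_volume_uL = 20)
  w <- do.call(rbind, lapply(0:10, function(k) {
    npos <- if (k < 4) rep(20000L, 4) else if (k == 10) rep(0L, 4)
    else rep(1000L - 90L * k, 4)
    mk_level(k, npos)
  }))
  class(w) <- c("well_table", "data.frame")
  series <- filter_dynamic_range(series_from_wells(w))
  expect_identical(nrow(series$levels), 6L)
  expect_identical(sort(series$excluded_levels$dilution_level),
                   c(0L, 1L, 2L, 3L, 10L))
  expect_identical(series$excluded_levels$reason[
    order(series$excluded_levels$dilution_level)],
    c(rep("oversaturated", 4), "weak_signal"))
})

test_that("filter is the identity on a clean series and errors when empty", {
  w <- make_detection_wells(c(1, 10, 100), det = c(10, 10, 10))
  series <- series_from_wells(w)
  filtered <- filter_dynamic_range(series)
  expect_equal(filtered$levels, series$levels)
  expect_identical(nrow(filtered$excluded_levels), 0L)

  sat <- well_table(platform = "droplet", dilution_level = 0L,
                    nominal_conc = 1e9, replicate_tech = 1:3,
                    n_total = 100L, n_positive = rep(100L, 3))
  expect_error(filter_dynamic_range(series_from_wells(sat)),
               "no interpretable dynamic range")
})

test_that("a single saturated level at a known index is excluded", {
  w <- make_detection_wells(c(0.5, 5, 50), det = c(10, 10, 10))
  sat <- well_table(platform = "droplet", dilution_level = 3L,
                    nominal_conc = 500, replicate_tech = 1:10,
                    n_total = 20000L, n_positive = rep(20000L, 10),
                    reaction_volume_uL = 20, template_volume_uL = 20)
  w <- rbind(w, sat); class(w) <- c("well_table", "data.frame")
  series <- filter_dynamic_range(series_from_wells(w))
  expect_identical(series$excluded_levels$dilution_level, 3L)
  expect_identical(series$excluded_levels$reason, "oversaturated")
})

test_that("fully detected series yields a flagged upper-bound LOD", {
  series <- series_from_wells(
    make_detection_wells(c(0.2, 2, 20), det = c(10, 10, 10)))
  lod <- estimate_lod(series)
  expect_true(lod$upper_bound_flag)
  expect_equal(lod$lod, 0.2)
})

test_that("LOD is bracketed by partially detected levels", {
  series <- series_from_wells(
    make_detection_wells(c(0.01, 0.1, 1), det = c(0, 5, 10)))
  lod <- estimate_lod(series, n_boot = 100, seed = 1)
  expect_gt(lod$lod, 0.1)
  expect_lt(lod$lod, 1)
  expect_false(lod$upper_bound_flag)
})

test_that("adding detections never increases the LOD", {
  conc <- c(0.01, 0.1, 1, 10)
  base_det <- c(0, 4, 9, 10)
  lod0 <- estimate_lod(series_from_wells(
    make_detection_wells(conc, base_det)), n_boot = 50, seed = 1)$lod
  for (lvl in 2:3) {
    more <- base_det; more[lvl] <- more[lvl] + 1L
    lod1 <- estimate_lod(series_from_wells(
      make_detection_wells(conc, more)), n_boot = 50, seed = 1)$lod
    expect_lte(lod1, lod0 + 1e-9)
  }
})

test_that("decreasing detection errors out with diagnostics", {
  series <- series_from_wells(
    make_detection_wells(c(0.01, 0.1, 1), det = c(10, 5, 1)))
  expect_error(estimate_lod(series), "not increasing")
})

test_that("constant low CV puts the LOQ at the lowest tested level", {
  tab <- make_cv_table(10^(0:4), rep(0.10, 5))
  res <- estimate_loq(build_dilution_series(tab))
  expect_true(res$loq_defined)
  expect_equal(res$loq, 1, tolerance = 1e-6)  # lowest level, grid start
  expect_equal(res$loq_empirical, 1)
})

test_that("CV never reaching the threshold leaves the LOQ undefined", {
  tab <- make_cv_table(10^(0:4), rep(0.50, 5))
  res <- estimate_loq(build_dilution_series(tab))
  expect_false(res$loq_defined)
  expect_true(is.na(res$loq))
  expect_true(is.na(res$loq_empirical))
})

test_that("a constructed CV crossing is recovered within one grid step", {
  # CV falls linearly in log10(conc) from 0.55 at 1 to 0.05 at 1e5,
  # crossing 0.35 at conc = 10^((0.55 - 0.35) / 0.10) = 100
  concs <- 10^(0:5)
  cvs <- 0.55 - 0.10 * log10(concs)
  res <- estimate_loq(build_dilution_series(make_cv_table(concs, cvs)))
  true_cross <- 100
  grid_step <- diff(log10(res$grid_range)) / 999
  expect_true(res$loq_defined)
  expect_lt(abs(log10(res$loq) - log10(true_cross)), grid_step + 1e-9)
  # exactly linear CV data: AIC tie resolved toward degree 1 over degree 3
  expect_identical(res$selected_degree, 1L)
})

test_that("LOQ is invariant to replicate order and monotone in variance", {
  concs <- 10^(0:5)
  cvs <- 0.55 - 0.10 * log10(concs)
  tab <- make_cv_table(concs, cvs)
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(estimate_loq(build_dilution_series(perm))$loq,
               estimate_loq(build_dilution_series(tab))$loq)
  inflated <- estimate_loq(build_dilution_series(
    make_cv_table(concs, cvs * 1.5)))$loq
  expect_gte(inflated, estimate_loq(build_dilution_series(tab))$loq)
})

test_that("too few usable levels is an explicit error", {
  tab <- make_cv_table(10^(0:2), rep(0.2, 3))
  expect_error(estimate_loq(build_dilution_series(tab)), "at least 5 levels")
})
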