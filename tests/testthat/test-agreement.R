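test_that("CCC closed forms: identity, shift, reversal", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ccc(paired_measurements(x, x), n_boot = 50, seed = 1)$ccc, 1)
  # population var 1, perfect correlation, shift 2: CCC = 2/(2 + 4) = 1/3
  z <- c(-1, 0, 1) * sqrt(3 / 2)
  expect_equal(ccc(paired_measurements(z, z + 2), n_boot = 50, seed = 1)$ccc,
               1 / 3)
  expect_equal(ccc(paired_measurements(z, -z), n_boot = 50, seed = 1)$ccc, -1)
})

test_that("CCC invariances hold on random data", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(20); y <- 0.7 * x + rnorm(20, 0, 0.5)
    p1 <- ccc(paired_measurements(x, y), n_boot = 10, seed = 1)
    p2 <- ccc(paired_measurements(y, x), n_boot = 10, seed = 1)
    expect_equal(p1$ccc, p2$ccc)                       # symmetry
    expect_lte(abs(p1$ccc), abs(p1$pearson_rho) + 1e-12)
    expect_lte(p1$ccc, 1)
    p3 <- ccc(paired_measurements(x + 3, y + 3), n_boot = 10, seed = 1)
    expect_equal(p3$ccc, p1$ccc)                       # common shift
  }
})

test_that("bootstrap CI is seeded and deterministic", {
  set.seed(8)
  x <- rlnorm(30, 2, 0.5); y <- x * rlnorm(30, 0, 0.1)
  a <- ccc(paired_measurements(x, y), n_boot = 300, seed = 42)
  b <- ccc(paired_measurements(x, y), n_boot = 300, seed = 42)
  expect_identical(a[c("ci_low", "ci_high")], b[c("ci_low", "ci_high")])
  expect_true(a$ci_low <= a$ccc && a$ccc <= a$ci_high)
  expect_error(ccc(paired_measurements(rep(1, 5), 1:5)), "zero variance")
})

test_that("constant differences collapse the Bland-Altman bands", {
  x <- c(10, 20, 30, 40); y <- x - 2.5
  ba <- bland_altman(paired_measurements(x, y))
  expect_equal(ba$bias, 2.5)
  expect_equal(ba$loa_low, 2.5)
  expect_equal(ba$loa_high, 2.5)
  expect_equal(ba$prop_bias_beta1, 0)
})

test_that("inverse-variance weighting follows the weighted-mean formula", {
  # group A: d = 1 +/- 0.1 (var 0.02); group B: d = 3 +/- 0.1*sqrt(3)
  # (var 0.06) -> weights 3:1 per pair, weighted bias (3*1 + 1*3)/4 = 1.5
  a <- 0.1
  x <- c(10 + 1 - a, 20 + 1 + a, 10 + 3 - a * sqrt(3), 20 + 3 + a * sqrt(3))
  y <- c(10, 20, 10, 20)
  p <- paired_measurements(x, y, group = c("A", "A", "B", "B"))
  ba <- bland_altman(p, weighted = TRUE)
  expect_equal(ba$bias, 1.5)
  expect_equal(unname(ba$weights[1] / ba$weights[3]), 3)
})

test_that("equal weights reduce the weighted bias to the classic one", {
  set.seed(13)
  x <- rnorm(12, 50, 5); y <- x - rnorm(12, 1, 0.5)
  g <- rep(1:3, each = 4)
  p <- paired_measurements(x, y, group = g)
  classic <- bland_altman(p, weighted = FALSE)
  # force equal weights: make within-group variances identical by using one
  # group's differences in every group
  d <- x - y
  d_eq <- rep(d[1:4], 3)
  p_eq <- paired_measurements(y + d_eq, y, group = g)
  ba_w <- bland_altman(p_eq, weighted = TRUE)
  ba_c <- bland_altman(p_eq, weighted = FALSE)
  expect_identical(length(unique(round(ba_w$weights, 12))), 1L)
  expect_equal(ba_w$bias, ba_c$bias, tolerance = 1e-12)
  expect_error(bland_altman(p, weighted = TRUE), NA)
  expect_error(bland_altman(paired_measurements(x, y), weighted = TRUE),
               "group")
})

test_that("singleton groups fall back to the pooled variance", {
  set.seed(2)
  x <- c(rnorm(4, 10), 30); y <- x - c(rnorm(4, 1, 0.3), 2)
  p <- paired_measurements(x, y, group = c(1, 1, 1, 1, 2))
  ba <- bland_altman(p, weighted = TRUE)
  expect_identical(length(unique(round(ba$weights, 12))), 1L)
})

test_that("paired test selection follows the normality of differences", {
  set.seed(17)
  x <- rlnorm(30, 3, 0.4)
  normal <- paired_measurements(x, x + rnorm(30, 0.5, 0.2))
  expect_identical(paired_test(normal)$name, "paired_t")
  heavy <- paired_measurements(x, x + rcauchy(30, 0, 0.5))
  expect_identical(paired_test(heavy)$name, "wilcoxon")
  same <- paired_measurements(x, x)
  res <- paired_test(same)
  expect_identical(res$name, "no_difference")
  expect_identical(res$p_value, 1)
})

test_that("heteroscedasticity flag tracks how spread scales with level", {
  set.seed(23)
  m <- seq(10, 500, length.out = 40)
  prop <- paired_measurements(m + m * 0.1 * rnorm(40), m)
  expect_true(heteroscedasticity_check(prop)$heteroscedastic)
  homo <- paired_measurements(m + rnorm(40, 0, 2), m)
  expect_false(heteroscedasticity_check(homo)$heteroscedastic)
  const <- paired_measurements(m + 3, m)
  expect_false(heteroscedasticity_check(const)$heteroscedastic)
})

test_that("additive bias is recovered with no spurious proportional bias", {
  set.seed(29)
  n <- 200
  x <- rlnorm(n, 4, 0.6)
  b <- 5
  y <- x + b + rnorm(n, 0, 1)   # additive bias only, homoscedastic
  p <- paired_measurements(y, x) # orientation: first axis minus second
  ba <- bland_altman(p)
  expect_equal(ba$bias, b, tolerance = 3 / sqrt(n))  # ~3 se of the mean
  expect_lt(abs(ba$prop_bias_beta1), 2 * ba$prop_bias_se)
})

test_that("compare_platforms wires the decision rule together", {
  set.seed(37)
  m <- rep(10^(1:5), each = 6)
  x <- m * rlnorm(30, 0, 0.08)
  y <- m * rlnorm(30, 0, 0.08) * 0.8
  res <- compare_platforms(x, y, group = rep(1:5, each = 6),
                           n_boot = 200, seed = 3)
  expect_s3_class(res, "agreement_result")
  expect_true(res$pairs$log_transformed)
  expect_lt(res$ccc$ccc, 1)
  expect_gt(res$ccc$ccc, 0.9)
  # multiplicative offset on the log scale is additive: bias ~ -log10(0.8)
  expect_equal(res$bland_altman_classic$bias, -log10(0.8), tolerance = 0.1)
  expect_identical(res$bland_altman$orientation, "nanoplate - droplet")
})
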