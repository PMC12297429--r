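test_that("identical seed and scenario reproduce the dataset exactly", {
  sc <- sim_scenario("dilution_series", n_levels = 4, replicates_tech = 3,
                     base_concentration = 1e5, seed = 11)
  p <- platform_profile("droplet")
  a <- simulate_dilution_series(sc, p)
  b <- simulate_dilution_series(sc, p)
  expect_identical(a, b)
  sc2 <- sim_scenario("dilution_series", n_levels = 4, replicates_tech = 3,
                      base_concentration = 1e5, seed = 12)
  expect_false(identical(a$n_positive,
                         simulate_dilution_series(sc2, p)$n_positive))
})

test_that("degenerate scenarios produce saturated / all-negative wells", {
  p <- platform_profile("droplet", partition_volume_cv = 0,
                        false_positive_rate = 0, false_negative_rate = 0)
  hot <- sim_scenario("dilution_series", base_concentration = 1e12,
                      n_levels = 1, replicates_tech = 3, pipetting_cv = 0,
                      seed = 1)
  w <- simulate_dilution_series(hot, p)
  expect_true(all(w$n_positive == w$n_total))
  cold <- sim_scenario("dilution_series", base_concentration = 0,
                       n_levels = 2, replicates_tech = 3, seed = 1)
  expect_true(all(simulate_dilution_series(cold, p)$n_positive == 0))
})

test_that("simulate -> quantify recovers the true concentration", {
  p <- platform_profile("droplet")
  base <- base_conc_for_lambda(0.1, p)
  sc <- sim_scenario("dilution_series", base_concentration = base,
                     n_levels = 1, replicates_tech = 100, seed = 5)
  q <- quantify_well(simulate_dilution_series(sc, p))
  expect_equal(mean(q$conc_template), base, tolerance = 0.02)
})

test_that("positive fraction follows the flip-adjusted Poisson law", {
  for (lambda in c(0.01, 0.5, 2)) {
    fpr <- 0.01; fnr <- 0.02
    p <- platform_profile("droplet", n_partitions = 20000L,
                          partition_volume_cv = 0,
                          false_positive_rate = fpr,
                          false_negative_rate = fnr)
    base <- base_conc_for_lambda(lambda, p)
    sc <- sim_scenario("dilution_series", base_concentration = base,
                       n_levels = 1, replicates_tech = 30, pipetting_cv = 0,
                       seed = round(100 * lambda) + 3)
    w <- simulate_dilution_series(sc, p)
    p_true <- -expm1(-lambda)
    p_adj <- p_true * (1 - fnr) + (1 - p_true * (1 - fnr)) * fpr
    frac <- w$n_positive / w$n_total
    mc_se <- sqrt(p_adj * (1 - p_adj) / (20000 * 30))
    expect_lt(abs(mean(frac) - p_adj), 5 * mc_se + 1e-6)
  }
})

test_that("noise-free cell samples carry exactly cells x copies-per-cell", {
  sc <- sim_scenario("cell_counts", copies_per_cell_cv = 0, culture_cv = 0,
                     pipetting_cv = 0, enzyme = "none",
                     cell_numbers = c(5, 100), replicates_bio = 2, seed = 3)
  w <- simulate_cell_samples(sc, platform_profile("droplet"))
  truth <- attr(w, "truth")
  expect_equal(truth$total_copies, truth$cell_number * 1e4)
  expect_equal(truth$true_conc_template, truth$total_copies / 100)
})

test_that("enzyme accessibility scales copies by construction", {
  p <- platform_profile("nanoplate")
  mk <- function(enz) {
    sc <- sim_scenario("cell_counts", enzyme = enz,
                       enzyme_accessibility = c(EcoRI = 0.8, HaeIII = 1.0),
                       cell_numbers = c(20, 100), replicates_bio = 2,
                       replicates_tech = 1, seed = 21)
    attr(simulate_cell_samples(sc, p), "truth")$total_copies
  }
  # substreams are independent of the enzyme label, so the ratio is exact
  expect_equal(mk("HaeIII") / mk("EcoRI"), rep(1.25, 4))
})

test_that("variance components order technical below biological CV", {
  # 100-cell samples: culture-state variation dominates between-bio spread,
  # pipetting + partition noise dominate within-extract spread
  p <- platform_profile("droplet")
  sc <- sim_scenario("cell_counts", cell_numbers = 100, replicates_bio = 12,
                     replicates_tech = 3, seed = 9)
  q <- quantify_well(simulate_cell_samples(sc, p))
  tech <- replicate_cv(q, "technical")
  bio <- replicate_cv(q, "biological")
  expect_gt(bio$cv, 0.10)          # tens of percent from culture factor
  expect_lt(median(tech$cv), bio$cv)
  expect_lt(median(tech$cv), 0.10) # pipetting-scale noise
})

test_that("restriction site scan finds documented motifs only", {
  expect_identical(find_restriction_sites("AAGAATTCAA", "EcoRI"), 2L)
  expect_identical(find_restriction_sites("AAAA", "HaeIII"), integer(0))
  expect_identical(find_restriction_sites("GGCCGGCC", "HaeIII"), c(0L, 4L))
  expect_identical(find_restriction_sites("ggccAA", "HaeIII"), 0L)
  expect_error(find_restriction_sites("GGNCC", "HaeIII"), "A,C,G,T")
  # property: every reported position carries the recognition sequence
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    for (enz in c("EcoRI", "HaeIII")) {
      site <- c(EcoRI = "GAATTC", HaeIII = "GGCC")[[enz]]
      pos <- find_restriction_sites(s, enz)
      for (j in pos)
        expect_identical(substr(s, j + 1, j + nchar(site)), site)
      # no missed occurrence: count against fixed-pattern reference
      ref <- gregexpr(site, s, fixed = TRUE)[[1]]
      expect_identical(length(pos), if (ref[1] == -1L) 0L else length(ref))
    }
  }
})

test_that("FASTA input feeds the site scan", {
  skip_if_not_installed("Biostrings")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">frag1", "AAGAATTCAAGGCC", ">frag2", "TTTT"), path)
  seqs <- read_fasta(path)
  expect_identical(names(seqs), c("frag1", "frag2"))
  expect_identical(find_restriction_sites(seqs[["frag1"]], "EcoRI"), 2L)
  expect_identical(find_restriction_sites(seqs[["frag1"]], "HaeIII"), 10L)
})
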