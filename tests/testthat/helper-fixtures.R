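# fixtures built in code, shared across test files

# independent brute-force oracle: drop M molecules uniformly into N partitions,
# return the number of occupied (positive) partitions
occupy_partitions <- function(M, N) {
  sum(tabulate(sample.int(N, M, replace = TRUE), nbins = N) > 0L)
}

# concentration table with exact per-level means and CVs: two replicates
# m*(1 -/+ cv/sqrt(2)) have sample mean m and sample CV cv
make_cv_table <- function(conc_levels, cvs, n_rep = 2L) {
  stopifnot(length(conc_levels) == length(cvs), n_rep == 2L)
  rows <- lapply(seq_along(conc_levels), function(i) {
    m <- conc_levels[i]; k <- cvs[i] / sqrt(2)
    data.frame(dilution_level = i - 1L,
               nominal_conc = conc_levels[i],
               conc_reaction = c(m * (1 - k), m * (1 + k)),
               status = "ok",
               template_volume_uL = 1, reaction_volume_uL = 1)
  })
  do.call(rbind, rows)
}

# well table for detection experiments: per level, `det` wells with a clear
# positive count and `n - det` wells with zero positives; nominal template
# concentration chosen so the reaction-scale nominal equals `conc`
make_detection_wells <- function(conc, det, n = 10L) {
  stopifnot(length(conc) == length(det))
  rows <- lapply(seq_along(conc), function(i) {
    npos <- c(rep(400L, det[i]), rep(0L, n - det[i]))
    well_table(platform = "droplet", sample_id = sprintf("L%02d", i),
               dilution_level = i - 1L, nominal_conc = conc[i],
               replicate_tech = seq_len(n),
               n_total = 20000L, n_positive = npos,
               partition_volume_nL = 0.85, reaction_volume_uL = 20,
               template_volume_uL = 20)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("well_table", "data.frame")
  out
}

# base template concentration giving mean copies-per-partition lambda on a
# given platform profile
base_conc_for_lambda <- function(lambda, profile, template_volume_uL = 1) {
  lambda / (profile$partition_volume_nL * 1e-3) *
    profile$reaction_volume_uL / template_volume_uL
}
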