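#' Define a simulation scenario
#'
#' Describes the experiment the synthetic-data generator should emulate.
#' Two modes are supported, mirroring the two experiment types the analysis
#' pipeline consumes:
#'
#' * `"dilution_series"` — a 1:10 serial dilution of a synthetic
#'   oligonucleotide stock, 11 levels with 10 technical replicates per level.
#'   The default `base_concentration` is the expected copy number of the
#'   measured 1.68 ng/uL stock (see [expected_copies()]), about 6.9e9
#'   copies/uL template.
#' * `"cell_counts"` — extracts from 5 to 100 ciliate cells (3 biological x 3
#'   technical replicates), with high per-cell rDNA copy numbers, lognormal
#'   intraspecific copy-number variability and a restriction-enzyme
#'   accessibility factor on the effective template.
#'
#' @param mode `"dilution_series"` or `"cell_counts"`.
#' @param base_concentration stock concentration in copies/uL template
#'   (dilution mode).
#' @param dilution_factor fold dilution between levels (> 1).
#' @param n_levels number of dilution levels.
#' @param replicates_tech technical replicates per level / extract.
#' @param cell_numbers cell counts per sample (cell mode).
#' @param replicates_bio biological replicates per cell count.
#' @param copies_per_cell_mean mean rDNA copies per cell.
#' @param copies_per_cell_cv intraspecific CV of per-cell copy number within
#'   one culture.
#' @param culture_cv CV of the shared culture-state factor that scales every
#'   cell of one biological replicate; this is what keeps
#'   between-biological-replicate CVs in the tens of percent even for
#'   100-cell samples, where independent per-cell variation would average
#'   out.
#' @param enzyme restriction enzyme label attached to the wells.
#' @param enzyme_accessibility named fractions in (0, 1] scaling the effective
#'   template by enzyme (models accessibility of the tandemly repeated gene).
#' @param elution_volume_uL extract elution volume (cell mode).
#' @param template_volume_uL template input per reaction; defaults to 1 uL
#'   (dilution) or 2 uL (cells).
#' @param pipetting_cv CV of the multiplicative pipetting error per replicate.
#' @param seed integer seed; the full dataset is reproducible from it.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(mode = c("dilution_series", "cell_counts"),
                         base_concentration = expected_copies(1.68),
                         dilution_factor = 10,
                         n_levels = 11L,
                         replicates_tech = NULL,
                         cell_numbers = c(5, 10, 20, 50, 100),
                         replicates_bio = 3L,
                         copies_per_cell_mean = 1e4,
                         copies_per_cell_cv = 0.30,
                         culture_cv = 0.25,
                         enzyme = "none",
                         enzyme_accessibility = c(EcoRI = 0.8, HaeIII = 1.0,
                                                  none = 1.0),
                         elution_volume_uL = 100,
                         template_volume_uL = NULL,
                         pipetting_cv = 0.02,
                         seed = 1L) {
  mode <- match.arg(mode)
  replicates_tech <- replicates_tech %||%
    switch(mode, dilution_series = 10L, cell_counts = 3L)
  template_volume_uL <- template_volume_uL %||%
    switch(mode, dilution_series = 1, cell_counts = 2)
  stopifnot(base_concentration >= 0, dilution_factor > 1, n_levels >= 1,
            replicates_tech >= 1, replicates_bio >= 1,
            copies_per_cell_mean > 0, copies_per_cell_cv >= 0,
            culture_cv >= 0,
            all(enzyme_accessibility > 0), all(enzyme_accessibility <= 1),
            elution_volume_uL > 0, template_volume_uL > 0, pipetting_cv >= 0)
  if (!enzyme %in% names(enzyme_accessibility))
    stop_input("no accessibility entry for enzyme '", enzyme, "'")
  structure(list(mode = mode, base_concentration = base_concentration,
                 dilution_factor = dilution_factor,
                 n_levels = as.integer(n_levels),
                 replicates_tech = as.integer(replicates_tech),
                 cell_numbers = cell_numbers,
                 replicates_bio = as.integer(replicates_bio),
                 copies_per_cell_mean = copies_per_cell_mean,
                 copies_per_cell_cv = copies_per_cell_cv,
                 culture_cv = culture_cv,
                 enzyme = enzyme,
                 enzyme_accessibility = enzyme_accessibility,
                 elution_volume_uL = elution_volume_uL,
                 template_volume_uL = template_volume_uL,
                 pipetting_cv = pipetting_cv, seed = as.integer(seed)),
            class = "sim_scenario")
}

# simulate one well's partition counts given the reaction-mix concentration
# (copies/uL) and a platform profile; partition volumes are Gamma with the
# profile CV, positives/negatives flipped by the profile error rates
simulate_partitions <- function(conc_reaction, profile, volume_scale = 1) {
  n <- profile$n_partitions
  v_mean <- profile$partition_volume_nL * 1e-3 * volume_scale  # uL
  cv <- profile$partition_volume_cv
  v <- if (cv > 0) {
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, rate = shape / v_mean)
  } else rep(v_mean, n)
  p_pos <- -expm1(-conc_reaction * v)
  pos <- stats::runif(n) < p_pos
  # misclassification: false negatives on positives, false positives on negatives
  if (profile$false_negative_rate > 0)
    pos[pos] <- stats::runif(sum(pos)) >= profile$false_negative_rate
  if (profile$false_positive_rate > 0) {
    neg <- which(!pos)
    pos[neg] <- stats::runif(length(neg)) < profile$false_positive_rate
  }
  sum(pos)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a dilution-series dPCR experiment
#'
#' For each dilution level `k` the true template concentration is
#' `base_concentration * dilution_factor^-k`. Each technical replicate
#' perturbs it by a unit-mean lognormal pipetting error, converts to
#' reaction-mix concentration through the template and reaction volumes, and
#' draws partition counts with Gamma-distributed partition volumes and the
#' profile's misclassification rates. Identical seed and scenario reproduce
#' the dataset exactly; random substreams are derived per well so draws do not
#' depend on labels such as the enzyme.
#'
#' @param scenario a [sim_scenario()] with mode `"dilution_series"`.
#' @param profile a [platform_profile()].
#' @return A `well_table` with one row per well; the attribute `"truth"` holds
#'   the per-well true template and reaction concentrations.
#' @export
#' @examples
#' sc <- sim_scenario("dilution_series", n_levels = 3, replicates_tech = 2,
#'                    base_concentration = 1e4, seed = 7)
#' simulate_dilution_series(sc, platform_profile("droplet"))
simulate_dilution_series <- function(scenario, profile) {
  stopifnot(inherits(scenario, "sim_scenario"),
            inherits(profile, "platform_profile"))
  if (scenario$mode != "dilution_series")
    stop_input("scenario mode must be 'dilution_series'")
  pip <- lnorm_unit(scenario$pipetting_cv)
  # one plate-level volume scale per simulated run (substream 0)
  vs <- with_seed(derive_seed(scenario$seed, 0L), {
    if (profile$volume_scale_sd > 0)
      stats::rlnorm(1, -profile$volume_scale_sd^2 / 2, profile$volume_scale_sd)
    else 1
  })
  rows <- list(); truth <- list(); idx <- 0L
  for (k in seq_len(scenario$n_levels) - 1L) {
    c_template <- scenario$base_concentration * scenario$dilution_factor^(-k)
    for (t in seq_len(scenario$replicates_tech)) {
      idx <- idx + 1L
      res <- with_seed(derive_seed(scenario$seed, idx), {
        e <- if (scenario$pipetting_cv > 0)
          stats::rlnorm(1, pip[["meanlog"]], pip[["sdlog"]]) else 1
        c_rxn <- c_template * e * scenario$template_volume_uL /
          profile$reaction_volume_uL
        list(c_obs = c_template * e, c_rxn = c_rxn,
             n_pos = simulate_partitions(c_rxn, profile, vs))
      })
      rows[[idx]] <- data.frame(
        well_id = sprintf("%s_L%02d_T%02d", profile$name, k, t),
        platform = profile$name, sample_id = sprintf("dil_L%02d", k),
        dilution_level = k, nominal_conc = c_template,
        replicate_tech = t, replicate_bio = 1L, enzyme = scenario$enzyme,
        n_total = profile$n_partitions, n_positive = res$n_pos,
        partition_volume_nL = profile$partition_volume_nL,
        reaction_volume_uL = profile$reaction_volume_uL,
        template_volume_uL = scenario$template_volume_uL,
        volume_scale = vs, cell_number = NA_real_,
        stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(well_id = rows[[idx]]$well_id,
                                 true_conc_template = c_template,
                                 observed_conc_template = res$c_obs,
                                 true_conc_reaction = res$c_rxn)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("well_table", "data.frame")
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Simulate cell-count dPCR samples
#'
#' Each biological replicate of a cell-count sample draws per-cell rDNA copy
#' numbers from a lognormal distribution (mean `copies_per_cell_mean`, CV
#' `copies_per_cell_cv`), sums them, and scales by the enzyme accessibility
#' fraction; the extract is eluted in `elution_volume_uL`. Technical
#' replicates re-pipette the same extract with lognormal pipetting noise and
#' re-partition it. Per-extract random substreams are derived from the seed
#' independently of the enzyme label, so two runs differing only in enzyme
#' share cell draws and differ exactly by the accessibility ratio in
#' expectation.
#'
#' @inheritParams simulate_dilution_series
#' @param scenario a [sim_scenario()] with mode `"cell_counts"`.
#' @return A `well_table`; attribute `"truth"` holds per-extract total copies
#'   and template concentrations.
#' @export
simulate_cell_samples <- function(scenario, profile) {
  stopifnot(inherits(scenario, "sim_scenario"),
            inherits(profile, "platform_profile"))
  if (scenario$mode != "cell_counts")
    stop_input("scenario mode must be 'cell_counts'")
  acc <- scenario$enzyme_accessibility[[scenario$enzyme]]
  cellpar <- lnorm_mean_cv(scenario$copies_per_cell_mean,
                           scenario$copies_per_cell_cv)
  cult <- lnorm_unit(scenario$culture_cv)
  pip <- lnorm_unit(scenario$pipetting_cv)
  vs <- with_seed(derive_seed(scenario$seed, 0L), {
    if (profile$volume_scale_sd > 0)
      stats::rlnorm(1, -profile$volume_scale_sd^2 / 2, profile$volume_scale_sd)
    else 1
  })
  rows <- list(); truth <- list(); idx <- 0L
  for (ci in seq_along(scenario$cell_numbers)) {
    cn <- scenario$cell_numbers[ci]
    for (b in seq_len(scenario$replicates_bio)) {
      extract_idx <- ci * 1000L + b
      total_copies <- with_seed(derive_seed(scenario$seed, extract_idx), {
        f_b <- if (scenario$culture_cv > 0)
          stats::rlnorm(1, cult[["meanlog"]], cult[["sdlog"]]) else 1
        per_cell <- if (scenario$copies_per_cell_cv > 0)
          sum(stats::rlnorm(cn, cellpar[["meanlog"]], cellpar[["sdlog"]]))
        else cn * scenario$copies_per_cell_mean
        f_b * per_cell
      }) * acc
      c_template <- total_copies / scenario$elution_volume_uL
      for (t in seq_len(scenario$replicates_tech)) {
        idx <- idx + 1L
        well_idx <- extract_idx * 100L + t
        res <- with_seed(derive_seed(scenario$seed, well_idx), {
          e <- if (scenario$pipetting_cv > 0)
            stats::rlnorm(1, pip[["meanlog"]], pip[["sdlog"]]) else 1
          c_rxn <- c_template * e * scenario$template_volume_uL /
            profile$reaction_volume_uL
          list(c_rxn = c_rxn, n_pos = simulate_partitions(c_rxn, profile, vs))
        })
        rows[[idx]] <- data.frame(
          well_id = sprintf("%s_C%03d_B%d_T%d", profile$name, cn, b, t),
          platform = profile$name, sample_id = sprintf("cells_%03d_B%d", cn, b),
          dilution_level = NA_integer_, nominal_conc = c_template,
          replicate_tech = t, replicate_bio = b, enzyme = scenario$enzyme,
          n_total = profile$n_partitions, n_positive = res$n_pos,
          partition_volume_nL = profile$partition_volume_nL,
          reaction_volume_uL = profile$reaction_volume_uL,
          template_volume_uL = scenario$template_volume_uL,
          volume_scale = vs, cell_number = cn,
          stringsAsFactors = FALSE)
        truth[[idx]] <- data.frame(well_id = rows[[idx]]$well_id,
                                   cell_number = cn, replicate_bio = b,
                                   total_copies = total_copies,
                                   true_conc_template = c_template,
                                   true_conc_reaction = res$c_rxn)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("well_table", "data.frame")
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Find restriction-enzyme recognition sites in a sequence
#'
#' Scans the forward strand for exact recognition-site matches (both supported
#' sites are palindromic, so the reverse strand adds nothing). Used to check
#' that a digestion enzyme does not cut inside the target amplicon.
#'
#' @param sequence a DNA string over `A`, `C`, `G`, `T` (case-insensitive).
#' @param enzyme `"EcoRI"` (GAATTC) or `"HaeIII"` (GGCC).
#' @return Integer vector of 0-based match start positions.
#' @export
#' @examples
#' find_restriction_sites("AAGAATTCAA", "EcoRI")  # 2
find_restriction_sites <- function(sequence, enzyme = c("EcoRI", "HaeIII")) {
  enzyme <- match.arg(enzyme)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_input("sequence must be a single character string")
  seq_up <- toupper(sequence)
  if (grepl("[^ACGT]", seq_up))
    stop_input("sequence contains characters outside {A,C,G,T}")
  site <- c(EcoRI = "GAATTC", HaeIII = "GGCC")[[enzyme]]
  hits <- gregexpr(site, seq_up, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` returning plain named
#' character strings suitable for [find_restriction_sites()].
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_input("reading FASTA requires the Biostrings package")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
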