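#' Construct a table of per-well partition records
#'
#' A well record holds everything needed to quantify one dPCR well: the counts
#' of analyzable and positive partitions, the partition and reaction volumes,
#' and the experimental labels (sample, dilution level, replicate structure,
#' platform, restriction enzyme). All arguments are recycled to a common
#' length, so a whole plate can be built in one call.
#'
#' @param well_id character label per well.
#' @param platform `"nanoplate"` or `"droplet"`.
#' @param sample_id sample label.
#' @param dilution_level integer index of the dilution step (0 = undiluted) or
#'   `NA` for non-series samples.
#' @param nominal_conc nominal template concentration in copies/uL, or `NA`.
#' @param replicate_tech,replicate_bio technical / biological replicate index
#'   (>= 1).
#' @param enzyme restriction enzyme used for template digestion: `"EcoRI"`,
#'   `"HaeIII"` or `"none"`.
#' @param n_total number of analyzable partitions (>= 1).
#' @param n_positive number of positive partitions, `0 <= n_positive <=
#'   n_total`.
#' @param partition_volume_nL mean volume of one partition in nanolitres.
#' @param reaction_volume_uL total reaction volume in microlitres.
#' @param template_volume_uL template DNA input volume in microlitres.
#' @param volume_scale plate-level multiplicative volume correction (houses the
#'   instrument-side volume precision factor; default 1).
#' @param cell_number number of cells in the extract for cell-count
#'   experiments, or `NA`.
#' @return A `data.frame` of class `well_table`, one row per well.
#' @export
#' @examples
#' well_table(n_total = 20000, n_positive = 10000)
well_table <- function(well_id = NULL,
                       platform = "nanoplate",
                       sample_id = "S1",
                       dilution_level = NA_integer_,
                       nominal_conc = NA_real_,
                       replicate_tech = 1L,
                       replicate_bio = 1L,
                       enzyme = "none",
                       n_total,
                       n_positive,
                       partition_volume_nL = 0.85,
                       reaction_volume_uL = 20,
                       template_volume_uL = 1,
                       volume_scale = 1,
                       cell_number = NA_real_) {
  df <- data.frame(
    well_id = well_id %||% paste0("W", seq_along(n_total)),
    platform = platform, sample_id = sample_id,
    dilution_level = dilution_level, nominal_conc = nominal_conc,
    replicate_tech = as.integer(replicate_tech),
    replicate_bio = as.integer(replicate_bio),
    enzyme = enzyme,
    n_total = as.integer(n_total), n_positive = as.integer(n_positive),
    partition_volume_nL = partition_volume_nL,
    reaction_volume_uL = reaction_volume_uL,
    template_volume_uL = template_volume_uL,
    volume_scale = volume_scale,
    cell_number = cell_number,
    stringsAsFactors = FALSE
  )
  validate_well_table(df)
  class(df) <- c("well_table", "data.frame")
  df
}

#' Validate a well table against its invariants
#'
#' Checks the structural invariants of per-well records: counts are
#' non-negative with `n_positive <= n_total`, all volumes are positive, the
#' template volume does not exceed the reaction volume, and the platform and
#' enzyme labels are known.
#'
#' @param df a data.frame with the columns of [well_table()].
#' @return `df`, invisibly, if valid; otherwise an error.
#' @export
validate_well_table <- function(df) {
  required <- c("platform", "n_total", "n_positive", "partition_volume_nL",
                "reaction_volume_uL", "template_volume_uL", "volume_scale")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_input("well table lacks columns: ", paste(missing, collapse = ", "))
  if (any(!df$platform %in% c("nanoplate", "droplet")))
    stop_input("platform must be 'nanoplate' or 'droplet'")
  if ("enzyme" %in% names(df) &&
      any(!df$enzyme %in% c("EcoRI", "HaeIII", "none")))
    stop_input("enzyme must be 'EcoRI', 'HaeIII' or 'none'")
  if (any(df$n_total < 1L)) stop_input("n_total must be >= 1")
  if (any(df$n_positive < 0L | df$n_positive > df$n_total))
    stop_input("n_positive must satisfy 0 <= n_positive <= n_total")
  vols <- c("partition_volume_nL", "reaction_volume_uL", "template_volume_uL",
            "volume_scale")
  for (v in vols)
    if (any(!is.finite(df[[v]]) | df[[v]] <= 0))
      stop_input(v, " must be positive and finite")
  if (any(df$template_volume_uL > df$reaction_volume_uL))
    stop_input("template_volume_uL must not exceed reaction_volume_uL")
  invisible(df)
}

#' Read / write well tables as CSV
#'
#' The interchange dialect is fixed: comma-separated, dot decimal separator,
#' UTF-8, mandatory header row with the column names of [well_table()].
#'
#' @param path file path.
#' @return `read_well_csv` returns a validated `well_table`;
#'   `write_well_csv` returns `path` invisibly.
#' @export
read_well_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0L) stop_input("empty well table: ", path)
  # all-NA columns come back logical; restore the documented types
  for (col in c("nominal_conc", "cell_number", "partition_volume_nL",
                "reaction_volume_uL", "template_volume_uL", "volume_scale"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  for (col in c("dilution_level", "replicate_tech", "replicate_bio",
                "n_total", "n_positive"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  validate_well_table(df)
  class(df) <- c("well_table", "data.frame")
  df
}

#' @rdname read_well_csv
#' @param df a `well_table`.
#' @export
write_well_csv <- function(df, path) {
  validate_well_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Platform measurement profiles
#'
#' Bundles the physical characteristics of a dPCR platform used by both the
#' quantification and the simulation modules. Defaults describe the two
#' platforms compared in the package: a 26,000-partition nanoplate system run
#' in 40 uL, and a droplet system generating up to 20,000 droplets of about
#' 0.85 nL in a 20 uL reaction. The nanoplate per-partition volume defaults to
#' `reaction_volume_uL / n_partitions` times `partitioned_fraction`, since the
#' instrument does not publish it.
#'
#' @param name `"nanoplate"` or `"droplet"`.
#' @param n_partitions number of partitions generated per well.
#' @param reaction_volume_uL reaction volume in uL.
#' @param partition_volume_nL mean partition volume in nL; `NULL` uses the
#'   platform default described above.
#' @param partitioned_fraction fraction of the reaction volume that ends up in
#'   analyzable nanoplate partitions.
#' @param partition_volume_cv coefficient of variation of individual partition
#'   volumes (simulation only).
#' @param false_positive_rate per-partition probability that a negative
#'   partition is called positive (simulation only).
#' @param false_negative_rate per-positive-partition probability of a missed
#'   call (simulation only).
#' @param volume_scale_sd lognormal sd of the plate-level volume scale factor
#'   (simulation only).
#' @return A list of class `platform_profile`.
#' @export
#' @examples
#' platform_profile("droplet")
#' platform_profile("nanoplate")$partition_volume_nL  # 40/26000 uL in nL
platform_profile <- function(name = c("nanoplate", "droplet"),
                             n_partitions = NULL,
                             reaction_volume_uL = NULL,
                             partition_volume_nL = NULL,
                             partitioned_fraction = 1,
                             partition_volume_cv = 0.05,
                             false_positive_rate = 0,
                             false_negative_rate = 0,
                             volume_scale_sd = 0) {
  name <- match.arg(name)
  n_partitions <- n_partitions %||% switch(name, nanoplate = 26000L,
                                           droplet = 20000L)
  reaction_volume_uL <- reaction_volume_uL %||% switch(name, nanoplate = 40,
                                                       droplet = 20)
  partition_volume_nL <- partition_volume_nL %||% switch(
    name,
    nanoplate = reaction_volume_uL / n_partitions * 1e3 * partitioned_fraction,
    droplet = 0.85
  )
  stopifnot(n_partitions >= 1, reaction_volume_uL > 0, partition_volume_nL > 0,
            partition_volume_cv >= 0,
            false_positive_rate >= 0, false_positive_rate < 1,
            false_negative_rate >= 0, false_negative_rate < 1,
            volume_scale_sd >= 0)
  structure(list(name = name, n_partitions = as.integer(n_partitions),
                 reaction_volume_uL = reaction_volume_uL,
                 partition_volume_nL = partition_volume_nL,
                 partition_volume_cv = partition_volume_cv,
                 false_positive_rate = false_positive_rate,
                 false_negative_rate = false_negative_rate,
                 volume_scale_sd = volume_scale_sd),
            class = "platform_profile")
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf("<platform_profile> %s: %d partitions of %.4g nL, %g uL reaction\n",
              x$name, x$n_partitions, x$partition_volume_nL,
              x$reaction_volume_uL))
  invisible(x)
}
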