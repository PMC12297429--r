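#' Build a run configuration
#'
#' Collects every tunable the pipeline uses, fills documented defaults, and
#' validates ranges. A configuration can come from a JSON or YAML file (one
#' top-level mapping with the argument names below) or be built in code.
#'
#' @param config optional path to a JSON/YAML file, or a named list; values
#'   given there override the defaults.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed driving simulation and bootstraps.
#' @param cv_threshold LOQ CV threshold (default 0.35).
#' @param detect_prob LOD detection probability (default 0.95).
#' @param max_degree maximum polynomial degree for model selection.
#' @param n_boot bootstrap replicates.
#' @param alpha significance level for test selection and flags.
#' @param ci_level confidence level for per-well intervals.
#' @param enzymes enzymes simulated for the cell-count experiment.
#' @param input optional list of CSV paths (`dilution_csv`, `cells_csv`,
#'   character vectors) to analyze instead of simulating.
#' @param scenario_dilution,scenario_cells optional [sim_scenario()] overrides
#'   (named lists of arguments).
#' @param plots write PNG plots (default TRUE).
#' @return A list of class `run_config`.
#' @export
run_config <- function(config = NULL, out_dir = "dpcr_run", seed = 1L,
                       cv_threshold = 0.35, detect_prob = 0.95,
                       max_degree = 3L, n_boot = 2000L, alpha = 0.05,
                       ci_level = 0.95, enzymes = c("EcoRI", "HaeIII"),
                       input = NULL, scenario_dilution = list(),
                       scenario_cells = list(), plots = TRUE) {
  defaults <- list(out_dir = out_dir, seed = as.integer(seed),
                   cv_threshold = cv_threshold, detect_prob = detect_prob,
                   max_degree = as.integer(max_degree),
                   n_boot = as.integer(n_boot), alpha = alpha,
                   ci_level = ci_level, enzymes = enzymes, input = input,
                   scenario_dilution = scenario_dilution,
                   scenario_cells = scenario_cells, plots = plots)
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_input("YAML configs require the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
      stop_input("unknown config fields: ", paste(unknown, collapse = ", "))
    defaults[names(config)] <- config
  }
  cfg <- defaults
  for (f in c("cv_threshold", "detect_prob", "alpha", "ci_level"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop_input(f, " must be in (0,1)")
  if (is.null(cfg$seed)) stop_input("seed is required")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

log_stage <- function(lines, stage, ...) {
  msg <- sprintf("stage=%s %s", stage, paste0(...))
  message(msg)
  c(lines, msg)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Sequences the full analysis: simulate (or load) partition-level data for
#' both platforms, quantify every well, estimate LOD and LOQ from the
#' dilution series, evaluate accuracy against analytically expected copy
#' numbers, summarize technical and biological precision, and compute
#' cross-platform agreement (paired test, CCC, Bland-Altman with the
#' heteroscedasticity-driven weighting rule). All tables, JSON results, plots
#' and a structured log are written under `config$out_dir`; re-running with
#' the same configuration and seed reproduces the JSON outputs byte for byte.
#'
#' @param config a [run_config()] (or anything accepted by its `config`
#'   argument).
#' @return Invisibly, a list with every stage result and the output paths.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- character()
  profiles <- list(nanoplate = platform_profile("nanoplate"),
                   droplet = platform_profile("droplet"))

  # --- stage: data (simulate or load) -------------------------------------
  wells <- list()
  if (!is.null(cfg$input)) {
    for (nm in names(cfg$input)) {
      for (p in cfg$input[[nm]]) {
        w <- read_well_csv(p)
        key <- sub("_csv$", "", nm)
        wells[[key]] <- rbind(wells[[key]], as.data.frame(w))
      }
    }
    for (key in names(wells)) class(wells[[key]]) <-
        c("well_table", "data.frame")
    lines <- log_stage(lines, "load", "tables=", length(wells), " wells=",
                       sum(vapply(wells, nrow, 1L)))
  } else {
    sc_dil <- do.call(sim_scenario, c(list(mode = "dilution_series",
                                           seed = cfg$seed),
                                      cfg$scenario_dilution))
    dil <- lapply(profiles, simulate_dilution_series, scenario = sc_dil)
    wells$dilution <- do.call(rbind, unname(lapply(dil, as.data.frame)))
    cells <- list()
    for (enz in cfg$enzymes) {
      sc <- do.call(sim_scenario, c(list(mode = "cell_counts", enzyme = enz,
                                         seed = cfg$seed),
                                    cfg$scenario_cells))
      for (p in names(profiles))
        cells[[paste(enz, p, sep = "_")]] <-
          as.data.frame(simulate_cell_samples(sc, profiles[[p]]))
    }
    wells$cells <- do.call(rbind, unname(cells))
    class(wells$dilution) <- class(wells$cells) <-
      c("well_table", "data.frame")
    lines <- log_stage(lines, "simulate", "dilution_wells=",
                       nrow(wells$dilution), " cell_wells=",
                       nrow(wells$cells), " seed=", cfg$seed)
  }

  # --- stage: quantify ----------------------------------------------------
  conc <- lapply(wells, quantify_well, ci_level = cfg$ci_level)
  for (key in names(conc)) {
    out_csv <- file.path(cfg$out_dir, paste0("concentrations_", key, ".csv"))
    utils::write.csv(conc[[key]], out_csv, row.names = FALSE)
    lines <- log_stage(lines, "quantify", "set=", key, " wells_in=",
                       nrow(conc[[key]]), " oversaturated=",
                       sum(conc[[key]]$status == "oversaturated"),
                       " below_detection=",
                       sum(conc[[key]]$status == "below_detection"))
  }

  # --- stage: sensitivity (per platform, dilution series) -----------------
  sensitivity <- list()
  if (!is.null(conc$dilution)) {
    for (p in unique(conc$dilution$platform)) {
      sub <- conc$dilution[conc$dilution$platform == p, , drop = FALSE]
      series <- filter_dynamic_range(build_dilution_series(sub))
      lod <- estimate_lod(series, detect_prob = cfg$detect_prob,
                          n_boot = cfg$n_boot, seed = cfg$seed)
      loq <- estimate_loq(series, cv_threshold = cfg$cv_threshold,
                          max_degree = cfg$max_degree)
      sensitivity[[p]] <- list(
        platform = p, lod = lod,
        loq = list(loq = loq$loq, loq_defined = loq$loq_defined,
                   loq_empirical = loq$loq_empirical,
                   cv_threshold = loq$cv_threshold,
                   selected_degree = loq$selected_degree,
                   model_table = loq$model_table[, c("degree", "aic",
                                                     "adj_r2")]),
        excluded_levels = series$excluded_levels)
      write_json_out(sensitivity[[p]],
                     file.path(cfg$out_dir, paste0("sensitivity_", p, ".json")))
      if (isTRUE(cfg$plots)) {
        grDevices::png(file.path(cfg$out_dir, paste0("cv_curve_", p, ".png")),
                       width = 700, height = 500)
        plot_cv_curve(loq, main = p)
        grDevices::dev.off()
      }
      lines <- log_stage(lines, "sensitivity", "platform=", p, " excluded=",
                         nrow(series$excluded_levels), " retained=",
                         nrow(series$levels), " cv_threshold=",
                         cfg$cv_threshold)
    }
  }

  # --- stage: accuracy (measured vs expected, dilution series) ------------
  accuracy <- list()
  if (!is.null(conc$dilution)) {
    for (p in unique(conc$dilution$platform)) {
      sub <- conc$dilution[conc$dilution$platform == p &
                             conc$dilution$status == "ok", , drop = FALSE]
      sub <- sub[is.finite(sub$nominal_conc) & sub$nominal_conc > 0, ,
                 drop = FALSE]
      if (length(unique(sub$nominal_conc)) >= cfg$max_degree + 2L) {
        accuracy[[p]] <- accuracy_regression(sub$nominal_conc,
                                             sub$conc_template,
                                             max_degree = cfg$max_degree)
        write_json_out(list(platform = p,
                            per_level = accuracy[[p]]$per_level,
                            regression = accuracy[[p]]$regression[
                              c("degree", "adjusted_r2", "aic",
                                "coefficients")]),
                       file.path(cfg$out_dir,
                                 paste0("accuracy_", p, ".json")))
        lines <- log_stage(lines, "accuracy", "platform=", p, " degree=",
                           accuracy[[p]]$regression$degree, " adj_r2=",
                           round(accuracy[[p]]$regression$adjusted_r2, 4))
      }
    }
  }

  # --- stage: precision (cells) -------------------------------------------
  precision <- NULL
  if (!is.null(conc$cells)) {
    precision <- list(technical = replicate_cv(conc$cells, "technical"),
                      biological = replicate_cv(conc$cells, "biological"))
    utils::write.csv(precision$technical,
                     file.path(cfg$out_dir, "precision_technical.csv"),
                     row.names = FALSE)
    utils::write.csv(precision$biological,
                     file.path(cfg$out_dir, "precision_biological.csv"),
                     row.names = FALSE)
    lines <- log_stage(lines, "precision", "technical_groups=",
                       nrow(precision$technical), " biological_groups=",
                       nrow(precision$biological))
  }

  # --- stage: agreement (nanoplate vs droplet) ----------------------------
  agreement <- list()
  pair_sets <- list()
  if (!is.null(conc$dilution))
    pair_sets$dilution <- align_platform_pairs(
      conc$dilution, c("dilution_level", "replicate_tech"))
  if (!is.null(conc$cells))
    for (enz in unique(conc$cells$enzyme))
      pair_sets[[paste0("cells_", enz)]] <- align_platform_pairs(
        conc$cells[conc$cells$enzyme == enz, , drop = FALSE],
        c("cell_number", "replicate_bio", "replicate_tech"))
  for (nm in names(pair_sets)) {
    ps <- pair_sets[[nm]]
    if (is.null(ps) || nrow(ps) < 6L) next
    agreement[[nm]] <- compare_platforms(ps$x, ps$y, group = ps$group,
                                         n_boot = cfg$n_boot,
                                         seed = cfg$seed,
                                         alpha = cfg$alpha)
    res <- agreement[[nm]]
    write_json_out(list(
      dataset = nm, n = res$ccc$n,
      ccc = res$ccc[c("ccc", "ci_low", "ci_high", "pearson_rho")],
      test = res$test,
      heteroscedastic_log_scale = res$heteroscedasticity$heteroscedastic,
      bland_altman = res$bland_altman[c("bias", "loa_low", "loa_high",
                                        "prop_bias_beta1", "prop_bias_p",
                                        "weighted", "orientation")],
      bland_altman_classic = res$bland_altman_classic[
        c("bias", "loa_low", "loa_high")]),
      file.path(cfg$out_dir, paste0("agreement_", nm, ".json")))
    if (isTRUE(cfg$plots)) {
      grDevices::png(file.path(cfg$out_dir,
                               paste0("bland_altman_", nm, ".png")),
                     width = 700, height = 500)
      plot_bland_altman(res$bland_altman, res$pairs, main = nm)
      grDevices::dev.off()
    }
    lines <- log_stage(lines, "agreement", "dataset=", nm, " pairs=",
                       res$ccc$n, " ccc=", round(res$ccc$ccc, 4),
                       " weighted_ba=", res$bland_altman$weighted)
  }

  # out_dir and input paths are machine-local; dropping them keeps the
  # snapshot byte-identical across re-runs of the same analysis
  write_json_out(unclass(cfg)[setdiff(names(cfg), c("input", "out_dir"))],
                 file.path(cfg$out_dir, "config.json"))
  writeLines(lines, file.path(cfg$out_dir, "log.txt"))
  invisible(list(config = cfg, wells = wells, concentrations = conc,
                 sensitivity = sensitivity, accuracy = accuracy,
                 precision = precision, agreement = agreement,
                 out_dir = cfg$out_dir))
}

# pair the two platforms' wells on shared labels; returns x = nanoplate,
# y = droplet concentrations plus a group label for weighting
align_platform_pairs <- function(conc, keys) {
  ok <- conc[conc$status == "ok", , drop = FALSE]
  a <- ok[ok$platform == "nanoplate", , drop = FALSE]
  b <- ok[ok$platform == "droplet", , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
  key_a <- do.call(paste, c(a[keys], sep = "|"))
  key_b <- do.call(paste, c(b[keys], sep = "|"))
  common <- intersect(key_a, key_b)
  if (!length(common)) return(NULL)
  ia <- match(common, key_a); ib <- match(common, key_b)
  data.frame(x = a$conc_template[ia], y = b$conc_template[ib],
             group = a[[keys[1L]]][ia], stringsAsFactors = FALSE)
}

#' Validate against a locally deposited real dataset
#'
#' Optional hook for users who have downloaded the deposited instrument
#' tables. Reads every CSV in `dir`, reports per-file parse status, and for
#' files that validate as well tables runs quantification plus the
#' sensitivity and agreement stages, printing the computed statistics next to
#' any user-supplied reference values. Nothing in the test suite requires
#' this data; an absent directory is a clean skip.
#'
#' @param dir path to the local copy of the deposited tables.
#' @param config a [run_config()] for thresholds and seeds.
#' @param reference optional named numeric vector of published values to
#'   print beside the computed ones.
#' @return Invisibly, a list with `skipped`, per-file `status`, and any
#'   computed `results`.
#' @export
validate_external <- function(dir, config = NULL, reference = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (!dir.exists(dir)) {
    message("external validation skipped: directory not found: ", dir)
    return(invisible(list(skipped = TRUE, status = NULL, results = NULL)))
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  status <- list(); results <- list()
  for (f in files) {
    parsed <- tryCatch(read_well_csv(f), error = function(e) e)
    if (inherits(parsed, "error")) {
      status[[basename(f)]] <- paste("parse error:",
                                     conditionMessage(parsed))
      next
    }
    status[[basename(f)]] <- "ok"
    qc <- quantify_well(parsed, ci_level = cfg$ci_level)
    res <- list(n_wells = nrow(qc))
    if (any(!is.na(qc$dilution_level))) {
      series <- tryCatch(filter_dynamic_range(build_dilution_series(qc)),
                         error = function(e) NULL)
      if (!is.null(series)) {
        res$lod <- tryCatch(
          estimate_lod(series, cfg$detect_prob, n_boot = cfg$n_boot,
                       seed = cfg$seed)$lod, error = function(e) NA_real_)
        res$loq <- tryCatch(
          estimate_loq(series, cfg$cv_threshold, cfg$max_degree)$loq,
          error = function(e) NA_real_)
      }
    }
    results[[basename(f)]] <- res
  }
  for (nm in names(status)) message(nm, ": ", status[[nm]])
  if (length(results)) {
    for (nm in names(results)) {
      r <- results[[nm]]
      message(sprintf("%s: n=%d LOD=%s LOQ=%s", nm, r$n_wells,
                      format(signif(r$lod %||% NA_real_, 3)),
                      format(signif(r$loq %||% NA_real_, 3))))
    }
    if (!is.null(reference))
      message("reference values: ",
              paste(names(reference), signif(reference, 3), sep = "=",
                    collapse = ", "))
  }
  invisible(list(skipped = FALSE, status = status, results = results))
}
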