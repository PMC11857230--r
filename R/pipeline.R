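# per-stage child seeds derived from the global seed: seed + 1000 * stage
# index (design = 1, simulate = 2, calibration = 3, matrix study = 4), so a
# stage can be rerun in isolation with a known seed
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("design", "simulate", "calibration", "matrix"))
  as.integer((seed + 1000L * idx) %% .Machine$integer.max)
}

#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end optimisation pipeline in one
#' validated list. A configuration round-trips through
#' [write_pipeline_config()] / [read_pipeline_config()] unchanged.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param n_runs Design size (default 60).
#' @param n_starts Random starts of the exchange optimizer (default 20).
#' @param n_replicates Bench replicates per design run (default 3).
#' @param alpha Significance threshold for backward elimination (default
#'   0.05).
#' @param top_k Length of the ranking top lists (default 10).
#' @param top_m Per-analyte best-performer set size (default 3).
#' @param noise_cv Simulated measurement CV (default 0.05).
#' @param response Response fitted: `"peak_area"` or `"area_ratio"`.
#' @param simulate Generate synthetic responses (`TRUE`) or load them from
#'   `response_file` (`FALSE`).
#' @param response_file CSV of measured responses when `simulate = FALSE`.
#' @param design_file Optional CSV of bench conditions; when given the design
#'   stage loads it instead of constructing one.
#' @param run_validation Also run the calibration/recovery stages (default
#'   `TRUE`).
#' @param space A [factor_space()] (default: the standard study space).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_runs = 60L, n_starts = 20L,
                            n_replicates = 3L, alpha = 0.05, top_k = 10L,
                            top_m = 3L, noise_cv = 0.05,
                            response = c("peak_area", "area_ratio"),
                            simulate = TRUE, response_file = NULL,
                            design_file = NULL, run_validation = TRUE,
                            space = default_factor_space()) {
  response <- match.arg(response)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_runs = as.integer(n_runs),
         n_starts = as.integer(n_starts),
         n_replicates = as.integer(n_replicates), alpha = alpha,
         top_k = as.integer(top_k), top_m = as.integer(top_m),
         noise_cv = noise_cv, response = response, simulate = simulate,
         response_file = response_file, design_file = design_file,
         run_validation = run_validation, space = space),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sp <- raw$space
  space <- factor_space(sp$ext_solvents, sp$ext_volumes, sp$disp_solvents,
                        sp$disp_volumes, sp$ref_ext, sp$ref_disp)
  pipeline_config(
    seed = raw$seed, n_runs = raw$n_runs, n_starts = raw$n_starts,
    n_replicates = raw$n_replicates, alpha = raw$alpha, top_k = raw$top_k,
    top_m = raw$top_m, noise_cv = raw$noise_cv, response = raw$response,
    simulate = raw$simulate, response_file = raw$response_file,
    design_file = raw$design_file, run_validation = raw$run_validation,
    space = space
  )
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$space <- unclass(config$space)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read / write pipeline CSV tables
#'
#' Plain UTF-8 CSV with '.' decimal separator; non-detects are an explicit
#' logical flag column, never zeros or blanks.
#'
#' @param design,responses,path Objects / file paths.
#' @param space Factor space used to validate a loaded design.
#' @param n_replicates Replication recorded on a loaded design.
#' @name pipeline_io
#' @export
write_design_csv <- function(design, path) {
  runs <- design$runs
  out <- do.call(rbind, lapply(seq_len(design$n_replicates), function(r) {
    cbind(runs, replicate = r)
  }))
  out <- out[order(out$run_id, out$replicate), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_design_csv <- function(path, space, n_replicates = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(n_replicates)) {
    n_replicates <- if ("replicate" %in% names(tab))
      max(tab$replicate) else 1L
  }
  runs <- unique(tab[, c("run_id", condition_columns)])
  as_design(runs, space, n_replicates = n_replicates)
}

#' @rdname pipeline_io
#' @export
write_response_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_response_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("run_id", "analyte", "peak_area", "area_ratio", "non_detect")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("response table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$non_detect <- as.logical(tab$non_detect)
  tab
}

#' Run the end-to-end DLLME optimisation pipeline
#'
#' Executes design construction (or loading), response simulation (or
#' loading), per-analyte full-model fits, backward elimination, full-grid
#' prediction, both rankings and consensus selection, then optionally the
#' calibration and matrix-effect validation stages. All intermediate tables
#' are written as CSV under `out_dir` together with a run log recording
#' seeds and versions. Identical configuration and seed give identical
#' outputs.
#'
#' Analytes whose observations are all non-detects are excluded from
#' modelling and ranking. If an extraction solvent yields non-detects in
#' every run (a failed dispersion), its level is dropped from the modelling
#' and prediction space, since no data support its effect.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param truths Optional named list of [ground_truth_model()]s for the
#'   simulation stage; default: the printed ethyl octanoate truth plus
#'   randomised truths for the remaining analytes.
#' @return List with `design`, `responses`, `fits`, `reduced`, `grid`,
#'   `by_total`, `by_counts`, `consensus`, `excluded_analytes`, and (when
#'   validation runs) `calibration` and `recovery`.
#' @export
run_pipeline <- function(config, out_dir = NULL, truths = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  space <- config$space

  # --- design ---------------------------------------------------------
  design <- if (!is.null(config$design_file)) {
    if (!file.exists(config$design_file)) {
      stop("design stage: design file not found: ", config$design_file,
           call. = FALSE)
    }
    read_design_csv(config$design_file, space,
                    n_replicates = config$n_replicates)
  } else {
    d <- d_optimal_design(space, full_model_spec(), n_runs = config$n_runs,
                          seed = stage_seed(config$seed, "design"),
                          n_starts = config$n_starts,
                          n_replicates = config$n_replicates)
    d
  }

  # --- responses ------------------------------------------------------
  if (config$simulate) {
    if (is.null(truths)) {
      truths <- default_ground_truths(space,
                                      seed = stage_seed(config$seed,
                                                        "simulate"),
                                      noise_cv = config$noise_cv)
      truths[["ethyl octanoate"]] <- ethyl_octanoate_truth(
        noise_cv = config$noise_cv,
        failing_solvents = "pentane")
    }
    sim_cfg <- synthetic_config(seed = stage_seed(config$seed, "simulate"),
                                n_replicates = config$n_replicates,
                                noise_cv = config$noise_cv)
    responses <- generate_design_responses(design, truths, sim_cfg,
                                           space = space)
  } else {
    if (is.null(config$response_file) || !file.exists(config$response_file)) {
      stop("simulate stage: synthetic generation is disabled and no ",
           "response table was found at '",
           if (is.null(config$response_file)) "<unset>"
           else config$response_file, "'", call. = FALSE)
    }
    responses <- read_response_csv(config$response_file)
  }

  # --- modelling space: drop everywhere-failing solvent levels --------
  run_solvent <- design$runs$ext_solvent[match(responses$run_id,
                                               design$runs$run_id)]
  det_by_solvent <- tapply(!responses$non_detect, run_solvent, any)
  live_solvents <- names(det_by_solvent)[det_by_solvent]
  live_solvents <- space$ext_solvents[space$ext_solvents %in% live_solvents]
  model_space <- if (length(live_solvents) < length(space$ext_solvents)) {
    factor_space(live_solvents, space$ext_volumes, space$disp_solvents,
                 space$disp_volumes,
                 ref_ext = if (space$ref_ext %in% live_solvents)
                   space$ref_ext else live_solvents[1],
                 ref_disp = space$ref_disp)
  } else space
  keep_runs <- design$runs$run_id[design$runs$ext_solvent %in% live_solvents]
  model_design <- as_design(
    design$runs[design$runs$run_id %in% keep_runs, , drop = FALSE],
    model_space, n_replicates = design$n_replicates)
  model_responses <- responses[responses$run_id %in% keep_runs, ,
                               drop = FALSE]

  # --- fit + eliminate ------------------------------------------------
  analytes <- unique(model_responses$analyte)
  detected <- vapply(analytes, function(a) {
    any(!model_responses$non_detect[model_responses$analyte == a])
  }, logical(1))
  excluded <- analytes[!detected]
  fits <- list()
  reduced <- list()
  for (a in analytes[detected]) {
    f <- fit_model(model_responses, model_design, full_model_spec(),
                   analyte = a, response = config$response)
    fits[[a]] <- f
    reduced[[a]] <- backward_eliminate(f, alpha = config$alpha)
  }

  # --- predict + rank + consensus -------------------------------------
  grid <- predict_grid(reduced, model_space)
  by_total <- rank_total_area(grid, k = config$top_k)
  by_counts <- rank_top3_counts(grid, top_m = config$top_m, k = config$top_k)
  consensus <- consensus_select(by_total, by_counts)

  result <- list(design = design, responses = responses, fits = fits,
                 reduced = reduced, grid = grid, by_total = by_total,
                 by_counts = by_counts, consensus = consensus,
                 excluded_analytes = excluded, model_space = model_space)

  # --- validation -----------------------------------------------------
  if (isTRUE(config$run_validation)) {
    cal_seed <- stage_seed(config$seed, "calibration")
    sim_cfg <- synthetic_config(seed = cal_seed,
                                n_replicates = config$n_replicates,
                                noise_cv = config$noise_cv)
    curves <- list()
    modelled <- analytes[detected]
    for (i in seq_along(modelled)) {
      a <- modelled[i]
      pts <- generate_calibration_samples(
        slope = 2, intercept = 0.01, sigma = 0.05,
        levels = sim_cfg$calibration_levels,
        n_duplicates = sim_cfg$n_cal_duplicates,
        seed = cal_seed + i, analyte = a)
      curves[[a]] <- fit_calibration(pts)
    }
    mat_seed <- stage_seed(config$seed, "matrix")
    baseline <- stats::setNames(rep(50, length(modelled)), modelled)
    factor_draw <- withr::with_seed(mat_seed,
      stats::runif(1, sim_cfg$matrix_effect_range[1],
                   sim_cfg$matrix_effect_range[2]))
    study <- generate_matrix_study(
      baseline_conc = baseline, spike_levels = sim_cfg$spike_levels,
      matrix_effect_factor = factor_draw, noise_cv = config$noise_cv,
      n_replicates = config$n_replicates, seed = mat_seed + 1,
      slopes = vapply(curves, function(cv) cv$slope, numeric(1)))
    result$calibration <- curves
    result$recovery <- recovery_report(study, curves)
    result$matrix_effect_factor <- factor_draw
  }

  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(result$design, file.path(out_dir, "design.csv"))
  write_response_csv(result$responses, file.path(out_dir, "responses.csv"))

  model_summary <- do.call(rbind, lapply(result$reduced, function(f) {
    data.frame(analyte = f$analyte,
               retained_terms = paste(as.character(f$spec), collapse = ";"),
               residual_sd = f$residual_sd, r_squared = f$r_squared,
               n_obs = f$n_obs, stringsAsFactors = FALSE)
  }))
  utils::write.csv(model_summary, file.path(out_dir, "models.csv"),
                   row.names = FALSE)

  grid <- result$grid
  long <- do.call(rbind, lapply(seq_along(grid$analytes), function(a) {
    data.frame(grid$conditions,
               analyte = grid$analytes[a],
               predicted_area = grid$predicted[, a],
               clamped = grid$clamped[, a],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(result$by_total, file.path(out_dir, "rank_total.csv"),
                   row.names = FALSE)
  utils::write.csv(result$by_counts, file.path(out_dir, "rank_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$consensus, file.path(out_dir, "consensus.csv"),
                   row.names = FALSE)

  if (!is.null(result$calibration)) {
    cal <- do.call(rbind, lapply(result$calibration, function(cv) {
      data.frame(analyte = cv$analyte, slope = cv$slope,
                 intercept = cv$intercept, r_squared = cv$r_squared,
                 sigma = cv$sigma, LOD = cv$lod, LOQ = cv$loq,
                 range_min = cv$linear_range[1],
                 range_max = cv$linear_range[2], stringsAsFactors = FALSE)
    }))
    utils::write.csv(cal, file.path(out_dir, "calibration.csv"),
                     row.names = FALSE)
    utils::write.csv(result$recovery, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
  }

  log_lines <- c(
    sprintf("dllmeopt %s on R %s",
            as.character(utils::packageVersion("dllmeopt")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("global seed: %d", config$seed),
    sprintf("stage seeds: design=%d simulate=%d calibration=%d matrix=%d",
            stage_seed(config$seed, "design"),
            stage_seed(config$seed, "simulate"),
            stage_seed(config$seed, "calibration"),
            stage_seed(config$seed, "matrix")),
    sprintf("design: %d runs x %d replicates", nrow(result$design$runs),
            result$design$n_replicates),
    sprintf("consensus: %s %g uL + %s %g uL",
            result$consensus$ext_solvent, result$consensus$ext_volume_ul,
            result$consensus$disp_solvent, result$consensus$disp_volume_ul)
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
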