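#' Ground-truth response model for simulation
#'
#' A ground-truth model holds the "true" linear predictor of an analyte's
#' peak area over the DLLME factor space, plus the noise and failure
#' structure used when simulating measurements: multiplicative Gaussian noise
#' with a fixed coefficient of variation, deterministic non-detects for
#' extraction solvents that fail to form a cloudy dispersion, and a minimum
#' reportable area below which a simulated peak is a non-detect.
#'
#' @param analyte Analyte name.
#' @param coefficients Named numeric vector; names are model-matrix column
#'   labels (see [model_matrix()]), e.g. `"(Intercept)"`, `"ext_solventDCM"`,
#'   `"ext_volume_ul"`, `"ext_solventpentane:ext_volume_ul"`.
#' @param noise_cv Coefficient of variation of the multiplicative measurement
#'   noise (fraction, e.g. 0.05). Zero gives an exact evaluator.
#' @param failing_solvents Character vector of extraction-solvent labels whose
#'   runs yield non-detects regardless of the linear predictor.
#' @param detection_floor Minimum reportable peak area; simulated areas below
#'   it are flagged non-detect.
#' @return An object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(analyte, coefficients, noise_cv = 0,
                               failing_solvents = character(0),
                               detection_floor = 0) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (detection_floor < 0) stop("detection_floor must be >= 0", call. = FALSE)
  structure(
    list(analyte = as.character(analyte),
         coefficients = coefficients,
         noise_cv = noise_cv,
         failing_solvents = as.character(failing_solvents),
         detection_floor = detection_floor),
    class = "ground_truth_model"
  )
}

#' The packaged ethyl octanoate truth model
#'
#' The reduced regression model for ethyl octanoate peak area (treatment
#' coding, chloroform and acetone references, raw-µL volumes): intercept
#' 58,296; extraction-solvent effects 36,300 (CH:P 2:1), 3872 (DCM), 13,362
#' (hexane), 173,542 (pentane); 36 per µL of extraction solvent; disperser
#' effects -29,513 (acetonitrile) and -20,206 (methanol); and
#' solvent-specific volume slopes -38, -18, +9 and -126 per µL for CH:P, DCM,
#' hexane and pentane. Useful as a noiseless oracle: with `noise_cv = 0` the
#' generator reproduces this linear predictor exactly at every condition.
#'
#' @param noise_cv,failing_solvents,detection_floor Passed to
#'   [ground_truth_model()].
#' @return A `ground_truth_model` for ethyl octanoate.
#' @export
ethyl_octanoate_truth <- function(noise_cv = 0,
                                  failing_solvents = character(0),
                                  detection_floor = 0) {
  ground_truth_model(
    analyte = "ethyl octanoate",
    coefficients = c(
      "(Intercept)" = 58296,
      "ext_solventCH:P 2:1" = 36300,
      "ext_solventDCM" = 3872,
      "ext_solventhexane" = 13362,
      "ext_solventpentane" = 173542,
      "ext_volume_ul" = 36,
      "disp_solventacetonitrile" = -29513,
      "disp_solventmethanol" = -20206,
      "ext_solventCH:P 2:1:ext_volume_ul" = -38,
      "ext_solventDCM:ext_volume_ul" = -18,
      "ext_solventhexane:ext_volume_ul" = 9,
      "ext_solventpentane:ext_volume_ul" = -126
    ),
    noise_cv = noise_cv,
    failing_solvents = failing_solvents,
    detection_floor = detection_floor
  )
}

#' Evaluate a ground-truth linear predictor
#'
#' @param truth A [ground_truth_model()].
#' @param conditions Data.frame of conditions.
#' @param space The [factor_space()].
#' @return Numeric vector of mean responses, one per condition.
#' @export
truth_predict <- function(truth, conditions, space) {
  stopifnot(inherits(truth, "ground_truth_model"))
  X <- model_matrix(conditions, full_model_spec(), space)
  missing <- setdiff(names(truth$coefficients), colnames(X))
  if (length(missing)) {
    stop("coefficient label(s) not constructible from the factor space: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.numeric(X[, names(truth$coefficients), drop = FALSE] %*%
               truth$coefficients)
}

#' The 36 wine-aroma target analytes
#'
#' Esters, alcohols and aldehydes, C6 compounds, fatty acids,
#' norisoprenoids/terpenes and volatile phenols typically targeted in wine
#' aroma profiling. Three of them (trans-2-hexen-1-ol, beta-citronellol,
#' geraniol) are flagged by [default_ground_truths()] as never detected.
#'
#' @return Character vector of 36 analyte names.
#' @export
default_analytes <- function() {
  c("1-butanol", "benzaldehyde", "benzyl alcohol", "isoamyl alcohol",
    "isobutanol", "methionol", "phenylethyl alcohol",
    "1-hexanol", "cis-2-hexen-1-ol", "cis-3-hexen-1-ol", "hexanal",
    "trans-2-hexen-1-ol", "trans-2-hexenal", "trans-3-hexen-1-ol",
    "ethyl decanoate", "ethyl hexanoate", "ethyl octanoate",
    "ethyl phenyl acetate", "hexyl acetate", "isoamyl acetate",
    "beta-phenylethyl acetate",
    "decanoic acid", "hexanoic acid", "isobutyric acid", "isovaleric acid",
    "octanoic acid",
    "geraniol", "linalool", "alpha-ionone", "nerol", "alpha-terpineol",
    "beta-citronellol", "beta-damascenone", "beta-ionone",
    "4-ethyl guaiacol", "4-ethyl phenol")
}

#' Configuration of a synthetic DLLME study
#'
#' Bundles the simulation parameters shared across the generators: the master
#' seed, replication, analyte panel, calibration layout, spike levels and
#' matrix-effect factors.
#'
#' @param seed Master seed for all generators.
#' @param n_replicates Bench replicates per design condition (default 3).
#' @param analytes Analyte panel (default: the 36 wine-aroma targets).
#' @param noise_cv Measurement coefficient of variation (default 0.05; bench
#'   repeatability below 10% RSD).
#' @param calibration_levels Strictly increasing spike concentrations for
#'   calibration (µg/L); default six levels.
#' @param n_cal_duplicates Replicates per calibration level (default 2).
#' @param spike_levels Named low/medium/high spike concentrations (µg/L) for
#'   recovery and matrix-effect studies.
#' @param matrix_effect_range Range the per-matrix recovery factor is drawn
#'   from (default 0.8--1.2).
#' @param is_area_nominal Nominal internal-standard peak area used to form
#'   area ratios.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_replicates = 3L,
                             analytes = default_analytes(),
                             noise_cv = 0.05,
                             calibration_levels = c(5, 10, 50, 100, 500, 1000),
                             n_cal_duplicates = 2L,
                             spike_levels = c(low = 20, medium = 100,
                                              high = 500),
                             matrix_effect_range = c(0.8, 1.2),
                             is_area_nominal = 1e5) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (is.unsorted(calibration_levels, strictly = TRUE)) {
    stop("calibration levels must be strictly increasing", call. = FALSE)
  }
  if (any(matrix_effect_range <= 0)) {
    stop("matrix-effect factors must be positive", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
         analytes = analytes, noise_cv = noise_cv,
         calibration_levels = calibration_levels,
         n_cal_duplicates = as.integer(n_cal_duplicates),
         spike_levels = spike_levels,
         matrix_effect_range = matrix_effect_range,
         is_area_nominal = is_area_nominal),
    class = "synthetic_config"
  )
}

#' Simulate peak-area responses for a design
#'
#' For every design run x replicate x analyte the mean response is the
#' ground-truth linear predictor at the run's condition; the observed area is
#' mean x (1 + e) with e ~ Normal(0, noise_cv^2), truncated below at zero.
#' Runs whose extraction solvent is in the truth's `failing_solvents`, and
#' simulated areas below the detection floor, are emitted as non-detects.
#' Deterministic given the config seed.
#'
#' @param design A `dllme_design` (see [d_optimal_design()]), or any list with
#'   a `runs` data.frame and `n_replicates`.
#' @param truths List of [ground_truth_model()]s.
#' @param config A [synthetic_config()]; its `n_replicates` overrides the
#'   design's when given.
#' @param space The [factor_space()]; defaults to the design's own.
#' @return A data.frame with columns `run_id`, `replicate`, `analyte`,
#'   `peak_area`, `is_area`, `area_ratio`, `non_detect`.
#' @export
generate_design_responses <- function(design, truths, config,
                                      space = design$space) {
  stopifnot(inherits(config, "synthetic_config"))
  if (inherits(truths, "ground_truth_model")) truths <- list(truths)
  runs <- design$runs
  n_rep <- config$n_replicates
  means <- lapply(truths, function(tr) truth_predict(tr, runs, space))

  withr::with_seed(config$seed, {
    out <- list()
    k <- 1L
    for (a in seq_along(truths)) {
      tr <- truths[[a]]
      for (rep_i in seq_len(n_rep)) {
        mu <- means[[a]]
        eps <- stats::rnorm(length(mu), 0, tr$noise_cv)
        area <- pmax(mu * (1 + eps), 0)
        is_area <- config$is_area_nominal *
          (1 + stats::rnorm(length(mu), 0, tr$noise_cv))
        failed <- runs$ext_solvent %in% tr$failing_solvents
        nd <- failed | area < tr$detection_floor
        area[nd] <- NA_real_
        out[[k]] <- data.frame(
          run_id = runs$run_id, replicate = rep_i, analyte = tr$analyte,
          peak_area = area, is_area = is_area,
          area_ratio = area / is_area, non_detect = nd,
          stringsAsFactors = FALSE
        )
        k <- k + 1L
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate an internal-standard calibration series
#'
#' Area ratios follow `intercept + slope * concentration` plus additive
#' Gaussian residual noise of standard deviation `sigma`, the structure the
#' downstream 3.3\eqn{\sigma}/S and 10\eqn{\sigma}/S limit formulas assume.
#'
#' @param slope True slope S (area-ratio per µg/L), positive.
#' @param intercept True intercept.
#' @param sigma True residual standard deviation.
#' @param levels Strictly increasing concentrations (µg/L); at least 3.
#' @param n_duplicates Replicates per level (default 2).
#' @param seed Seed.
#' @param analyte Optional analyte label stored in the table.
#' @return Data.frame with columns `analyte`, `level_index`, `concentration`,
#'   `area_ratio`, and attributes `true_slope`, `true_sigma` for closed-form
#'   checks.
#' @export
generate_calibration_samples <- function(slope, intercept = 0, sigma = 0,
                                         levels, n_duplicates = 2L, seed = 1L,
                                         analyte = NA_character_) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  if (length(unique(levels)) < 3L) {
    stop("at least 3 distinct calibration levels are required for a ",
         "fittable curve", call. = FALSE)
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("calibration levels must be strictly increasing", call. = FALSE)
  }
  conc <- rep(levels, each = n_duplicates)
  ratio <- withr::with_seed(seed,
    intercept + slope * conc + stats::rnorm(length(conc), 0, sigma))
  out <- data.frame(
    analyte = analyte,
    level_index = rep(seq_along(levels), each = n_duplicates),
    concentration = conc,
    area_ratio = ratio,
    stringsAsFactors = FALSE
  )
  attr(out, "true_slope") <- slope
  attr(out, "true_sigma") <- sigma
  out
}

#' Simulate a paired spiked/unspiked matrix-effect study
#'
#' Each matrix carries a baseline concentration `Cb` per analyte and a
#' recovery factor; the unspiked sample measures `Cb` and the spiked sample
#' `Cb + factor * Cs`, each perturbed by multiplicative noise, so the true
#' recovery of the study is `factor * 100` percent. Measurements are reported
#' as area ratios through a per-analyte calibration slope.
#'
#' @param baseline_conc Named numeric vector: baseline concentration (µg/L)
#'   per analyte.
#' @param spike_levels Named numeric vector of spike concentrations Cs (µg/L),
#'   e.g. `c(low = 20, medium = 100, high = 500)`.
#' @param matrix_effect_factor Recovery factor of the matrix (e.g. 0.9 for a
#'   suppressive matrix), positive.
#' @param noise_cv Multiplicative noise CV.
#' @param n_replicates Replicates per sample (default 3).
#' @param seed Seed.
#' @param slopes Named calibration slopes per analyte (default 1, i.e. area
#'   ratio equals concentration).
#' @param matrix_id Label for the matrix.
#' @return Data.frame with columns `matrix_id`, `analyte`, `spiked`, `level`,
#'   `spike_conc`, `replicate`, `area_ratio`.
#' @export
generate_matrix_study <- function(baseline_conc, spike_levels,
                                  matrix_effect_factor = 1,
                                  noise_cv = 0, n_replicates = 3L, seed = 1L,
                                  slopes = NULL, matrix_id = "matrix1") {
  if (any(spike_levels <= 0)) stop("spike levels must be positive",
                                   call. = FALSE)
  if (matrix_effect_factor <= 0) stop("matrix-effect factor must be positive",
                                      call. = FALSE)
  analytes <- names(baseline_conc)
  if (is.null(analytes)) stop("baseline_conc must be named by analyte",
                              call. = FALSE)
  if (is.null(slopes)) slopes <- stats::setNames(rep(1, length(analytes)),
                                                 analytes)
  lev_names <- names(spike_levels)
  if (is.null(lev_names)) lev_names <- as.character(seq_along(spike_levels))

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      level = lev_names,
                      spiked = c(FALSE, TRUE),
                      analyte = analytes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cs <- spike_levels[grid$level]
  cb <- baseline_conc[grid$analyte]
  true_conc <- ifelse(grid$spiked, cb + matrix_effect_factor * cs, cb)
  ratio_mean <- slopes[grid$analyte] * true_conc
  ratio <- withr::with_seed(seed,
    ratio_mean * (1 + stats::rnorm(length(ratio_mean), 0, noise_cv)))
  out <- data.frame(
    matrix_id = matrix_id,
    analyte = grid$analyte,
    spiked = grid$spiked,
    level = grid$level,
    spike_conc = as.numeric(cs),
    replicate = grid$replicate,
    area_ratio = pmax(ratio, 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Randomised ground-truth panel for the 36 wine-aroma analytes
#'
#' Draws one plausible ground-truth model per analyte: a log-normal overall
#' area scale, moderate solvent-type effects (chloroform-reference levels
#' drawn mostly unfavourable, acetonitrile favourable, methanol unfavourable),
#' a positive extraction-volume slope and small solvent-specific volume
#' interactions. This emulates the qualitative findings of chloroform +
#' acetonitrile + large extraction volume performing best, while leaving the
#' exact optimum to the draw. Three analytes (trans-2-hexen-1-ol,
#' beta-citronellol, geraniol) are marked never-detected; pentane is marked a
#' failing solvent for every analyte (no stable cloudy dispersion).
#'
#' @param space A [factor_space()] (default: the standard study space).
#' @param seed Seed.
#' @param noise_cv Noise CV recorded on every truth (default 0.05).
#' @param pentane_fails If `TRUE` (default) pentane runs are non-detects.
#' @return Named list of [ground_truth_model()]s, one per analyte.
#' @export
default_ground_truths <- function(space = default_factor_space(), seed = 1L,
                                  noise_cv = 0.05, pentane_fails = TRUE) {
  analytes <- default_analytes()
  never_detected <- c("trans-2-hexen-1-ol", "beta-citronellol", "geraniol")
  ext_levels <- setdiff(space$ext_solvents, space$ref_ext)
  disp_levels <- setdiff(space$disp_solvents, space$ref_disp)
  max_vol <- max(space$ext_volumes)

  withr::with_seed(seed, {
    truths <- lapply(analytes, function(a) {
      scale <- exp(stats::rnorm(1, log(5e4), 0.6))
      co <- c("(Intercept)" = scale)
      for (lev in ext_levels) {
        co[paste0("ext_solvent", lev)] <- scale * stats::runif(1, -0.35, 0.05)
      }
      for (lev in disp_levels) {
        co[paste0("disp_solvent", lev)] <-
          if (lev == "acetonitrile") scale * stats::runif(1, 0.05, 0.30)
          else scale * stats::runif(1, -0.30, -0.02)
      }
      co["ext_volume_ul"] <- scale * stats::runif(1, 0.1, 0.4) / max_vol
      for (lev in ext_levels) {
        co[paste0("ext_solvent", lev, ":ext_volume_ul")] <-
          scale * stats::rnorm(1, 0, 0.03) / max_vol
      }
      failing <- character(0)
      if (pentane_fails && "pentane" %in% space$ext_solvents) {
        failing <- "pentane"
      }
      if (a %in% never_detected) failing <- space$ext_solvents
      ground_truth_model(a, co, noise_cv = noise_cv,
                         failing_solvents = failing)
    })
    names(truths) <- analytes
    truths
  })
}
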