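#' Limits of detection and quantification
#'
#' `LOD = 3.3 * sigma / S` and `LOQ = 10 * sigma / S`, where `sigma` is the
#' residual standard deviation of the calibration line and `S` its slope, so
#' `LOQ/LOD = 10/3.3` whenever the LOD is positive.
#'
#' @param sigma Residual standard deviation of the calibration regression
#'   (area-ratio units), non-negative.
#' @param slope Calibration slope (area-ratio per µg/L), positive.
#' @return Named numeric vector `c(LOD = ..., LOQ = ...)` in concentration
#'   units.
#' @export
lod_loq <- function(sigma, slope) {
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (sigma < 0) stop("residual standard deviation must be >= 0",
                      call. = FALSE)
  c(LOD = 3.3 * sigma / slope, LOQ = 10 * sigma / slope)
}

#' Fit an internal-standard calibration curve
#'
#' Least-squares line of area ratio on spiked concentration. The residual
#' standard deviation uses the n - 2 degrees of freedom of simple linear
#' regression; r-squared is the squared Pearson correlation of fitted and
#' observed ratios (identical to the coefficient of determination here). LOD
#' and LOQ follow [lod_loq()]; the linear range is the span of calibration
#' concentrations.
#'
#' @param points Calibration table for one analyte with columns
#'   `concentration` and `area_ratio` (see
#'   [generate_calibration_samples()]).
#' @param analyte Analyte label; defaults to the table's `analyte` column if
#'   present.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `sigma`, `lod`, `loq`, `linear_range`,
#'   `n_points`.
#' @export
fit_calibration <- function(points, analyte = NULL) {
  if (is.null(analyte)) {
    analyte <- if ("analyte" %in% names(points))
      unique(points$analyte)[1] else NA_character_
  }
  conc <- points$concentration
  ratio <- points$area_ratio
  if (length(unique(conc)) < 3L) {
    stop("calibration for '", analyte, "' needs at least 3 distinct ",
         "concentration levels", call. = FALSE)
  }
  if (stats::sd(conc) == 0) {
    stop("zero concentration spread; calibration line is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(ratio ~ conc)
  # summary.lm warns on an exactly collinear (noiseless) calibration line;
  # zero residual sd is a supported degenerate case here
  fit_summary <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    stop("calibration for '", analyte, "' has non-positive slope; ",
         "response is not increasing with concentration", call. = FALSE)
  }
  sigma <- fit_summary$sigma
  if (!is.finite(sigma)) sigma <- 0
  limits <- lod_loq(sigma, slope)
  structure(
    list(analyte = analyte,
         slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = fit_summary$r.squared,
         sigma = sigma,
         lod = unname(limits["LOD"]),
         loq = unname(limits["LOQ"]),
         linear_range = range(conc),
         n_points = length(conc)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration: %s  ratio = %.4g + %.4g * conc  (r2 = %.4f, n = %d)\n",
    x$analyte, x$intercept, x$slope, x$r_squared, x$n_points))
  cat(sprintf("  sigma = %.4g, LOD = %.4g, LOQ = %.4g, range = %g-%g ug/L\n",
              x$sigma, x$lod, x$loq, x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Convert an area ratio to concentration with a reporting qualifier
#'
#' Inverts the calibration line, `(ratio - intercept) / slope`, and
#' qualifies the result: `below_LOD` under the detection limit, `below_LOQ`
#' between the limits, `above_range` beyond the calibrated span, `ok`
#' otherwise.
#'
#' @param area_ratio Numeric vector of area ratios.
#' @param curve A [fit_calibration()] result.
#' @return Data.frame with columns `concentration` and `qualifier`.
#' @export
quantify <- function(area_ratio, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (area_ratio - curve$intercept) / curve$slope
  qualifier <- rep("ok", length(conc))
  qualifier[conc > curve$linear_range[2]] <- "above_range"
  qualifier[conc < curve$loq] <- "below_LOQ"
  qualifier[conc < curve$lod] <- "below_LOD"
  data.frame(concentration = conc, qualifier = qualifier,
             stringsAsFactors = FALSE)
}

#' Spike recovery
#'
#' `R = (Co - Cb) / Cs * 100`: measured concentration in the spiked matrix
#' minus the unspiked baseline, relative to the spiked amount, in percent.
#'
#' @param co Measured concentration in the spiked matrix.
#' @param cb Measured concentration in the unspiked matrix.
#' @param cs Spiked concentration, positive.
#' @return Recovery in percent (vectorised).
#' @export
recovery <- function(co, cb, cs) {
  if (any(cs <= 0)) stop("spiked concentration must be positive",
                         call. = FALSE)
  (co - cb) / cs * 100
}

#' Intra- and inter-day precision (RSD)
#'
#' Relative standard deviation, `sd/mean * 100`, with the sample (n - 1)
#' standard deviation. The intra-day RSD is the mean of the within-day RSDs;
#' the inter-day RSD pools all measurements across days.
#'
#' @param values Numeric measurements.
#' @param day Day label per measurement (default: all one day).
#' @return List with `intra_day_rsd`, `inter_day_rsd`, `per_day_rsd` and
#'   `n_extractions`.
#' @export
precision <- function(values, day = rep(1L, length(values))) {
  if (length(values) < 2L) {
    stop("precision needs at least 2 measurements", call. = FALSE)
  }
  if (any(tabulate(factor(day)) < 2L)) {
    stop("every day needs at least 2 measurements", call. = FALSE)
  }
  rsd <- function(x) {
    m <- mean(x)
    if (m == 0) stop("RSD undefined: mean of measurements is zero",
                     call. = FALSE)
    stats::sd(x) / m * 100
  }
  per_day <- tapply(values, day, rsd)
  list(intra_day_rsd = mean(per_day),
       inter_day_rsd = rsd(values),
       per_day_rsd = per_day,
       n_extractions = length(values))
}

#' Summarise a matrix-effect study into recovery records
#'
#' Quantifies every measurement of a paired spiked/unspiked study through the
#' analyte's calibration, averages replicates, and applies [recovery()] per
#' analyte x level.
#'
#' @param study Table from [generate_matrix_study()] (columns `matrix_id`,
#'   `analyte`, `spiked`, `level`, `spike_conc`, `replicate`, `area_ratio`).
#' @param curves Named list of [fit_calibration()] curves per analyte; if
#'   `NULL`, area ratios are taken as concentrations (unit slope, zero
#'   intercept).
#' @return Data.frame with one row per matrix x analyte x level: `Co`, `Cb`,
#'   `Cs`, `recovery_pct` and the replicate RSD of the spiked measurements.
#' @export
recovery_report <- function(study, curves = NULL) {
  to_conc <- function(analyte, ratio) {
    if (is.null(curves)) return(ratio)
    quantify(ratio, curves[[analyte]])$concentration
  }
  groups <- unique(study[, c("matrix_id", "analyte", "level", "spike_conc")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- study$matrix_id == g$matrix_id & study$analyte == g$analyte &
      study$level == g$level
    spiked <- to_conc(g$analyte, study$area_ratio[sel & study$spiked])
    unspiked <- to_conc(g$analyte, study$area_ratio[sel & !study$spiked])
    data.frame(
      matrix_id = g$matrix_id, analyte = g$analyte, level = g$level,
      Co = mean(spiked), Cb = mean(unspiked), Cs = g$spike_conc,
      recovery_pct = recovery(mean(spiked), mean(unspiked), g$spike_conc),
      spiked_rsd = if (length(spiked) > 1 && mean(spiked) != 0)
        stats::sd(spiked) / mean(spiked) * 100 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
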