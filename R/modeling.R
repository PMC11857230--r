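#' Wrap a table of conditions as a design
#'
#' Builds a `dllme_design` from an explicit run table, e.g. one read from a
#' CSV of bench conditions rather than constructed by [d_optimal_design()].
#'
#' @param conditions Data.frame of condition columns (optionally with a
#'   `run_id` column; one is added if absent).
#' @param space The [factor_space()].
#' @param n_replicates Replicates per run (default 1).
#' @return A `dllme_design`.
#' @export
as_design <- function(conditions, space, n_replicates = 1L) {
  check_conditions(conditions, space)
  runs <- conditions
  if (!"run_id" %in% names(runs)) {
    runs <- cbind(run_id = seq_len(nrow(runs)), runs)
  }
  if (anyDuplicated(runs$run_id)) stop("run ids must be unique", call. = FALSE)
  rownames(runs) <- NULL
  structure(list(runs = runs, n_replicates = as.integer(n_replicates),
                 spec = NULL, space = space, log_d = NA_real_),
            class = "dllme_design")
}

# core OLS on a prebuilt coding; term p-values by partial F-tests
fit_ols_core <- function(conditions, y, spec, space, analyte = NA_character_) {
  X <- model_matrix(conditions, spec, space)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) {
    stop("model for '", analyte, "' is underdetermined: ", n,
         " usable observations for ", p, " model columns", call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("rank-deficient model matrix for '", analyte,
         "'; collinear column(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- as.numeric(X %*% beta)
  rss <- sum((y - fitted)^2)
  df_res <- n - p
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- colnames(X)

  # effectively-zero residuals (noiseless data fitted with a superset of the
  # truth) make the F ratio 0/0; resolve by comparing RSS changes to a
  # relative floor instead
  noiseless_tol <- 1e-9 * max(tss, 1)

  term_pvalues <- vapply(spec, function(term) {
    reduced <- model_spec(setdiff(spec, term))
    Xr <- model_matrix(conditions, reduced, space)
    qr_r <- qr(Xr)
    rss_r <- sum(qr.resid(qr_r, y)^2)
    df_num <- p - ncol(Xr)
    if (rss < noiseless_tol) {
      return(if (rss_r - rss < noiseless_tol) 1 else 0)
    }
    f <- ((rss_r - rss) / df_num) / (rss / df_res)
    stats::pf(f, df_num, df_res, lower.tail = FALSE)
  }, numeric(1))
  names(term_pvalues) <- as.character(spec)

  structure(
    list(analyte = analyte, spec = spec, coefficients = beta,
         std_errors = se, term_pvalues = term_pvalues,
         residual_sd = sqrt(sigma2), df_residual = df_res, n_obs = n,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         space = space, conditions = conditions, y = y),
    class = "dllme_fit"
  )
}

#' Fit the response-surface regression for one analyte
#'
#' Ordinary least squares of the measured response on the model matrix of the
#' design conditions. Non-detect rows are excluded (a failed extraction is
#' not a zero measurement). Each non-intercept term's p-value is the partial
#' F-test of the nested model omitting that whole term, so categorical terms
#' are tested with all their dummy columns at once.
#'
#' @param responses Response table as produced by
#'   [generate_design_responses()] (columns `run_id`, `analyte`, `peak_area`,
#'   `area_ratio`, `non_detect`).
#' @param design A `dllme_design` whose `runs` carry the conditions.
#' @param spec A [model_spec()] (default: the full response-surface model).
#' @param analyte Which analyte to fit; may be omitted when the table holds a
#'   single analyte.
#' @param response `"peak_area"` (default) or `"area_ratio"`.
#' @return An object of class `dllme_fit`.
#' @export
fit_model <- function(responses, design, spec = full_model_spec(),
                      analyte = NULL, response = c("peak_area", "area_ratio")) {
  response <- match.arg(response)
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  if (is.null(analyte)) {
    analyte <- unique(responses$analyte)
    if (length(analyte) != 1L) {
      stop("response table holds ", length(analyte),
           " analytes; supply `analyte`", call. = FALSE)
    }
  }
  rows <- responses[responses$analyte == analyte, , drop = FALSE]
  if (!nrow(rows)) stop("no responses for analyte '", analyte, "'",
                        call. = FALSE)
  rows <- rows[!rows$non_detect, , drop = FALSE]
  if (!nrow(rows)) {
    stop("analyte '", analyte, "' is unmodellable: all observations are ",
         "non-detects", call. = FALSE)
  }
  m <- match(rows$run_id, design$runs$run_id)
  if (anyNA(m)) stop("response run_id(s) absent from the design: ",
                     paste(unique(rows$run_id[is.na(m)]), collapse = ", "),
                     call. = FALSE)
  conditions <- design$runs[m, condition_columns, drop = FALSE]
  fit_ols_core(conditions, rows[[response]], spec, design$space,
               analyte = analyte)
}

#' Backward elimination of non-significant terms
#'
#' Starting from a fitted model, repeatedly removes the single eligible term
#' with the largest partial-F p-value at or above `alpha` and refits, until
#' every remaining term is significant. Whole terms are removed atomically
#' (all dummy columns of a categorical factor together). With `heredity` on
#' (weak heredity, the default), a main effect cannot be removed while any
#' retained interaction or quadratic term involves its factor. The
#' intercept-only model is a valid terminal state.
#'
#' @param fit A `dllme_fit` from [fit_model()].
#' @param alpha Significance threshold (default 0.05).
#' @param heredity Protect main effects of retained higher-order terms
#'   (default `TRUE`).
#' @return A `dllme_fit` for the reduced model, refitted on the same data.
#' @export
backward_eliminate <- function(fit, alpha = 0.05, heredity = TRUE) {
  stopifnot(inherits(fit, "dllme_fit"))
  repeat {
    terms <- as.character(fit$spec)
    if (!length(terms)) return(fit)
    eligible <- terms
    if (heredity) {
      protected_factors <- unique(unlist(lapply(
        terms[vapply(terms, is_compound_term, logical(1))], term_factors)))
      eligible <- terms[vapply(terms, function(t) {
        is_compound_term(t) || !(term_factors(t) %in% protected_factors)
      }, logical(1))]
    }
    if (!length(eligible)) return(fit)
    pv <- fit$term_pvalues[eligible]
    worst <- eligible[which.max(pv)]
    if (pv[which.max(pv)] < alpha) return(fit)
    reduced <- model_spec(setdiff(terms, worst))
    fit <- fit_ols_core(fit$conditions, fit$y, reduced, fit$space,
                        analyte = fit$analyte)
  }
}

#' @export
print.dllme_fit <- function(x, ...) {
  cat(sprintf("Response-surface fit: %s (n = %d, R^2 = %.4f, sigma = %.4g)\n",
              x$analyte, x$n_obs, x$r_squared, x$residual_sd))
  cat("terms:", if (length(x$spec)) paste(as.character(x$spec),
                                          collapse = ", ")
      else "(intercept only)", "\n")
  print(data.frame(coefficient = x$coefficients,
                   std_error = x$std_errors))
  invisible(x)
}

#' Predict mean response of a fitted model at new conditions
#'
#' @param object A `dllme_fit`.
#' @param newdata Data.frame of conditions.
#' @param ... Unused.
#' @return Numeric vector of raw (unclamped) linear-predictor values.
#' @export
predict.dllme_fit <- function(object, newdata, ...) {
  X <- model_matrix(newdata, object$spec, object$space)
  as.numeric(X %*% object$coefficients)
}
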