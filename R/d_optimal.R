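# log det(X'X) of a model-matrix row subset; -Inf when rank-deficient.
# Comparisons between designs happen on this scale: on raw-microlitre coding
# the determinant itself can exceed double range for the 25-column model.
logdet_xtx <- function(X) {
  if (nrow(X) < ncol(X)) return(-Inf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) return(-Inf)
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

#' Log D-criterion of a design
#'
#' `log det(X'X)` for the design's model matrix, the scale on which the
#' exchange optimizer compares designs (the determinant itself overflows
#' double precision for large raw-coded model matrices). Returns `-Inf` for a
#' rank-deficient design.
#'
#' @inheritParams d_criterion
#' @return A scalar, possibly `-Inf`.
#' @export
d_criterion_log <- function(conditions, spec, space) {
  logdet_xtx(model_matrix(conditions, spec, space))
}

#' Construct an exact D-optimal design by Fedorov exchange
#'
#' Selects `n_runs` conditions (repetition allowed) from the full candidate
#' grid of the factor space so as to maximise det(X'X) of the model matrix.
#' A multi-start Fedorov exchange is used: from each random starting design,
#' every run is repeatedly considered for exchange against every candidate
#' point, accepting the single best improving swap, until no exchange
#' improves the criterion; the best design over all starts is returned.
#' Deterministic given `seed`; ties between equal-criterion designs are broken
#' by first-found order.
#'
#' @param space A [factor_space()].
#' @param spec A [model_spec()] (default: the full response-surface model).
#' @param n_runs Number of runs; must be at least the number of model-matrix
#'   columns or the model is inestimable.
#' @param seed Integer seed controlling all random starts.
#' @param n_starts Number of random starting designs (default 20).
#' @param n_replicates Replication each selected condition will receive at the
#'   bench (recorded on the design; default 3).
#' @return An object of class `dllme_design`: a list with `runs` (data.frame
#'   of `run_id` plus condition columns), `n_replicates`, `spec`, `space`, and
#'   `log_d` (the achieved log D-criterion).
#' @export
d_optimal_design <- function(space, spec = full_model_spec(), n_runs,
                             seed = 1L, n_starts = 20L, n_replicates = 3L) {
  stopifnot(inherits(space, "factor_space"))
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  candidates <- enumerate_grid(space)
  Xc <- model_matrix(candidates, spec, space)
  p <- ncol(Xc)
  ncand <- nrow(Xc)
  if (n_runs < p) {
    stop("model is inestimable: n_runs (", n_runs,
         ") is less than the number of model parameters (", p, ")",
         call. = FALSE)
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)

  # the exchange runs on column-scaled candidates: raw-microlitre coding
  # spans seven orders of magnitude and makes X'X numerically singular.
  # Scaling is fixed across designs, so the criterion ordering is unchanged;
  # log det(X'X) = log det(Xs'Xs) + 2 * sum(log(scale)).
  col_scale <- sqrt(colMeans(Xc^2))
  Xs <- sweep(Xc, 2, col_scale, "/")

  best_idx <- NULL
  best_logdet <- -Inf
  withr::with_seed(seed, {
    for (start in seq_len(n_starts)) {
      idx <- random_nonsingular_start(Xs, n_runs)
      res <- fedorov_exchange(Xs, idx)
      if (res$logdet > best_logdet + 1e-9) {
        best_logdet <- res$logdet
        best_idx <- res$idx
      }
    }
  })
  best_logdet <- best_logdet + 2 * sum(log(col_scale))
  if (is.null(best_idx)) {
    stop("could not find a nonsingular starting design; ",
         "the candidate set cannot support the model", call. = FALSE)
  }
  runs <- candidates[best_idx, , drop = FALSE]
  rownames(runs) <- NULL
  runs <- cbind(run_id = seq_len(nrow(runs)), runs)
  structure(
    list(runs = runs, n_replicates = as.integer(n_replicates),
         spec = spec, space = space, log_d = best_logdet),
    class = "dllme_design"
  )
}

random_nonsingular_start <- function(Xc, n_runs, max_tries = 100L) {
  ncand <- nrow(Xc)
  for (try in seq_len(max_tries)) {
    idx <- sample.int(ncand, n_runs, replace = n_runs > ncand)
    if (qr(Xc[idx, , drop = FALSE])$rank == ncol(Xc)) return(idx)
  }
  NULL
}

# one multi-pass Fedorov exchange from a nonsingular start
fedorov_exchange <- function(Xc, idx, max_passes = 100L, tol = 1e-9) {
  if (is.null(idx)) return(list(idx = NULL, logdet = -Inf))
  n_runs <- length(idx)
  M <- crossprod(Xc[idx, , drop = FALSE])
  Minv <- solve(M)
  logdet <- as.numeric(determinant(M, logarithm = TRUE)$modulus)

  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(n_runs)) {
      xi <- Xc[idx[i], ]
      A <- Xc %*% Minv                      # ncand x p
      dj <- rowSums(A * Xc)                 # variance function at candidates
      di <- sum(xi * (Minv %*% xi))
      dij <- as.numeric(A %*% xi)
      # det ratio for swapping run i against each candidate j
      delta <- dj - (di * dj - dij^2) - di
      j <- which.max(delta)
      if (delta[j] > tol) {
        xj <- Xc[j, ]
        M <- M + tcrossprod(xj) - tcrossprod(xi)
        Minv <- solve(M)
        logdet <- logdet + log1p(delta[j])
        idx[i] <- j
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(idx = idx, logdet = logdet)
}

#' @export
print.dllme_design <- function(x, ...) {
  cat(sprintf("D-optimal DLLME design: %d runs x %d replicates, log|X'X| = %.3f\n",
              nrow(x$runs), x$n_replicates, x$log_d))
  print(utils::head(x$runs, 10))
  if (nrow(x$runs) > 10) cat("... and", nrow(x$runs) - 10, "more runs\n")
  invisible(x)
}
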