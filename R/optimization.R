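#' Predict every analyte over the full condition grid
#'
#' Evaluates each fitted model's linear predictor at every condition of the
#' factor space and replaces negative predictions with zero (peak areas are
#' physically non-negative), flagging where clamping occurred. Factors whose
#' terms were eliminated from a model leave its predictions unchanged across
#' their levels.
#'
#' @param models List of `dllme_fit` objects (see [fit_model()]).
#' @param space A [factor_space()].
#' @return An object of class `prediction_grid`: list with `conditions` (the
#'   enumerated grid), `predicted` (conditions x analytes matrix, clamped),
#'   `raw` (unclamped), `clamped` (logical matrix) and `analytes`.
#' @export
predict_grid <- function(models, space) {
  if (inherits(models, "dllme_fit")) models <- list(models)
  grid <- enumerate_grid(space)
  analytes <- vapply(models, function(m) m$analyte, character(1))
  raw <- vapply(models, function(m) predict(m, grid), numeric(nrow(grid)))
  raw <- matrix(raw, nrow = nrow(grid),
                dimnames = list(NULL, analytes))
  structure(
    list(conditions = grid, predicted = pmax(raw, 0), raw = raw,
         clamped = raw < 0, analytes = analytes),
    class = "prediction_grid"
  )
}

condition_key <- function(conditions) {
  paste(conditions$ext_solvent, conditions$ext_volume_ul,
        conditions$disp_solvent, conditions$disp_volume_ul, sep = "|")
}

#' Rank conditions by predicted total peak area
#'
#' Sums the clamped predictions over all analytes per condition and returns
#' the top `k` conditions by that total. Ties are broken by the deterministic
#' enumeration order of the grid.
#'
#' @param grid A [predict_grid()] result.
#' @param k How many conditions to return (default 10).
#' @return Data.frame of the top conditions with `total_area` and `rank`
#'   columns, sorted descending.
#' @export
rank_total_area <- function(grid, k = 10L) {
  stopifnot(inherits(grid, "prediction_grid"))
  totals <- rowSums(grid$predicted)
  ord <- order(-totals, seq_along(totals))
  top <- utils::head(ord, k)
  out <- grid$conditions[top, , drop = FALSE]
  out$total_area <- totals[top]
  out$rank <- seq_along(top)
  rownames(out) <- NULL
  out
}

#' Rank conditions by how often they are in an analyte's top m
#'
#' For each analyte, the `top_m` conditions by predicted value are its best
#' performers (competition ranking: conditions tied with the m-th best are
#' all included). Conditions are then ranked by the number of analytes that
#' selected them.
#'
#' @param grid A [predict_grid()] result.
#' @param top_m Size of each analyte's best-performer set (default 3).
#' @param k How many conditions to return (default 10).
#' @return Data.frame of the top conditions with `top3_count` and `rank`
#'   columns, sorted by descending count.
#' @export
rank_top3_counts <- function(grid, top_m = 3L, k = 10L) {
  stopifnot(inherits(grid, "prediction_grid"))
  n_cond <- nrow(grid$conditions)
  counts <- integer(n_cond)
  for (a in seq_along(grid$analytes)) {
    v <- grid$predicted[, a]
    m <- min(top_m, n_cond)
    threshold <- sort(v, decreasing = TRUE)[m]
    counts <- counts + (v >= threshold)
  }
  ord <- order(-counts, seq_len(n_cond))
  top <- utils::head(ord, k)
  out <- grid$conditions[top, , drop = FALSE]
  out$top3_count <- counts[top]
  out$rank <- seq_along(top)
  rownames(out) <- NULL
  out
}

#' Select the consensus optimal condition from both rankings
#'
#' Intersects the total-area and top-m-count top lists. Intersecting
#' conditions are ordered by combined standing (the sum of their two ranks);
#' among conditions of equal standing the one consuming less total solvent
#' (extraction + disperser volume) is preferred, then grid enumeration order.
#'
#' @param by_total Output of [rank_total_area()].
#' @param by_counts Output of [rank_top3_counts()].
#' @return One-row data.frame: the consensus condition with its two ranks.
#' @export
consensus_select <- function(by_total, by_counts) {
  if (!nrow(by_total) || !nrow(by_counts)) {
    stop("both ranking lists must be non-empty", call. = FALSE)
  }
  key_t <- condition_key(by_total)
  key_c <- condition_key(by_counts)
  shared <- intersect(key_t, key_c)
  if (!length(shared)) {
    stop("the two ranking criteria share no top conditions; inspect both ",
         "rankings before selecting an optimum", call. = FALSE)
  }
  it <- match(shared, key_t)
  ic <- match(shared, key_c)
  cand <- by_total[it, condition_columns, drop = FALSE]
  cand$rank_total <- by_total$rank[it]
  cand$rank_counts <- by_counts$rank[ic]
  standing <- cand$rank_total + cand$rank_counts
  solvent_use <- cand$ext_volume_ul + cand$disp_volume_ul
  pick <- order(standing, solvent_use, it)[1]
  out <- cand[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}
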