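test_that("grid predictions reproduce the reduced model arithmetic", {
  sp <- default_factor_space()
  fx <- eo_noiseless_responses(sp)
  fit <- fit_model(fx$responses, fx$design, model_spec(eo_terms()))
  grid <- predict_grid(fit, sp)
  condition_at <- function(es, ev, ds, dv) {
    which(grid$conditions$ext_solvent == es &
            grid$conditions$ext_volume_ul == ev &
            grid$conditions$disp_solvent == ds &
            grid$conditions$disp_volume_ul == dv)
  }
  i <- condition_at("chloroform", 2000, "acetonitrile", 1000)
  expect_equal(unname(grid$predicted[i, 1]), 100783, tolerance = 1e-8)
  expect_false(grid$clamped[i, 1])
  # disperser volume was eliminated: predictions identical across its levels
  expect_equal(grid$predicted[condition_at("chloroform", 2000,
                                           "acetonitrile", 500), 1],
               grid$predicted[condition_at("chloroform", 2000,
                                           "acetonitrile", 1500), 1],
               tolerance = 1e-9)
  expect_equal(unname(grid$predicted[condition_at("pentane", 500,
                                                  "acetone", 500), 1]),
               186838, tolerance = 1e-8)
})

test_that("negative predictions are clamped to zero and flagged", {
  sp <- toy_quant_space(c(1, 2, 3, 4))
  design <- full_grid_design(sp)
  y <- 5 - 2 * design$runs$ext_volume_ul   # negative beyond volume 2.5
  fit <- fit_model(response_table(design$runs$run_id, y), design,
                   model_spec("ext_volume"))
  grid <- predict_grid(fit, sp)
  expect_equal(grid$predicted[, 1], pmax(grid$raw[, 1], 0))
  expect_identical(grid$clamped[, 1], grid$raw[, 1] < 0)
  expect_true(any(grid$clamped))
  expect_true(all(grid$predicted >= 0))
})

test_that("total-area ranking matches brute-force sums with stable ties", {
  sp <- toy_quant_space(c(1, 2, 3))   # 3 conditions
  vals <- cbind(a1 = c(5, 1, 0), a2 = c(0, 1, 5))
  grid <- manual_grid(vals, sp)
  top2 <- rank_total_area(grid, k = 2)
  expect_equal(top2$total_area, c(5, 5))
  # tie broken by enumeration order: condition 1 before condition 3
  expect_equal(top2$ext_volume_ul, c(1, 3))

  zero <- manual_grid(matrix(0, 3, 2), sp)
  expect_equal(rank_total_area(zero, k = 3)$ext_volume_ul, c(1, 2, 3))

  # single-analyte grid ranks by that analyte's own predictions
  single <- manual_grid(cbind(c(2, 9, 4)), sp)
  expect_equal(rank_total_area(single, k = 3)$ext_volume_ul, c(2, 3, 1))
})

test_that("top-m count ranking agrees with an independent enumeration", {
  for (seed in 1:5) {
    set.seed(seed)
    sp <- toy_quant_space(1:6)
    vals <- matrix(sample(0:20, 6 * 4, replace = TRUE), 6, 4)
    grid <- manual_grid(vals, sp)
    counts <- rank_top3_counts(grid, top_m = 3, k = 6)
    oracle <- brute_top_m_counts(pmax(vals, 0), 3)
    expect_equal(counts$top3_count[order(counts$ext_volume_ul)],
                 oracle)
    # conservation: total count equals the summed top-m set sizes
    set_sizes <- vapply(seq_len(ncol(vals)), function(a) {
      sum(brute_top_m_counts(pmax(vals[, a, drop = FALSE], 0), 3))
    }, numeric(1))
    expect_equal(sum(counts$top3_count), sum(set_sizes))
  }
})

test_that("top-m ties broaden the selected set", {
  sp <- toy_quant_space(1:4)
  # analyte 2 is constant: it selects every condition
  vals <- cbind(c(4, 3, 2, 1), rep(7, 4))
  counts <- rank_top3_counts(manual_grid(vals, sp), top_m = 3, k = 4)
  by_cond <- counts$top3_count[order(counts$ext_volume_ul)]
  expect_equal(by_cond, c(2, 2, 2, 1))
  # saturation: top_m = number of conditions selects everything
  sat <- rank_top3_counts(manual_grid(vals, sp), top_m = 4, k = 4)
  expect_equal(sat$top3_count, rep(2, 4))
})

test_that("consensus selection intersects rankings and prefers less solvent", {
  sp <- default_factor_space()
  g <- enumerate_grid(sp)
  pick <- function(i, rank) {
    out <- g[i, , drop = FALSE]
    out$rank <- rank
    out
  }
  # identical top lists: head wins
  lst <- do.call(rbind, list(pick(10, 1), pick(20, 2)))
  expect_equal(consensus_select(lst, lst)$ext_solvent, g$ext_solvent[10])

  # equal standing, different solvent budgets: the leaner condition wins
  i_1000 <- which(g$ext_solvent == "chloroform" & g$ext_volume_ul == 2000 &
                    g$disp_solvent == "acetonitrile" &
                    g$disp_volume_ul == 1000)
  i_1500 <- which(g$ext_solvent == "chloroform" & g$ext_volume_ul == 2000 &
                    g$disp_solvent == "acetonitrile" &
                    g$disp_volume_ul == 1500)
  a <- rbind(pick(i_1000, 1), pick(i_1500, 2))
  b <- rbind(pick(i_1500, 1), pick(i_1000, 2))
  res <- consensus_select(a, b)
  expect_equal(res$disp_volume_ul, 1000)

  expect_error(consensus_select(pick(1, 1), pick(2, 1)), "inspect")
})

test_that("grid prediction is invariant to enumeration order of fits", {
  sp <- default_factor_space()
  fx <- eo_noiseless_responses(sp)
  f1 <- fit_model(fx$responses, fx$design, model_spec(eo_terms()))
  grid_a <- predict_grid(list(f1), sp)
  # conditions supplied to the model in shuffled order give the same surface
  set.seed(1)
  shuffled <- fx$design$runs[sample(nrow(fx$design$runs)), ]
  d2 <- as_design(shuffled, sp)
  f2 <- fit_model(fx$responses, d2, model_spec(eo_terms()))
  grid_b <- predict_grid(list(f2), sp)
  expect_equal(grid_a$predicted, grid_b$predicted, tolerance = 1e-8)
})
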