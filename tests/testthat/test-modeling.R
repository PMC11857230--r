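test_that("OLS recovers an exact line with zero residual", {
  sp <- toy_quant_space(c(1, 2, 3, 4))
  design <- full_grid_design(sp)
  y <- 2 + 3 * design$runs$ext_volume_ul
  fit <- fit_model(response_table(design$runs$run_id, y), design,
                   model_spec("ext_volume"))
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("noiseless grid responses reproduce the reduced truth exactly", {
  sp <- default_factor_space()
  fx <- eo_noiseless_responses(sp)
  fit <- fit_model(fx$responses, fx$design, model_spec(eo_terms()))
  truth <- ethyl_octanoate_truth()$coefficients
  expect_equal(fit$coefficients[names(truth)], truth, tolerance = 1e-8)
  # refitting with the full model also recovers the truth (absent terms at 0)
  full <- fit_model(fx$responses, fx$design, full_model_spec())
  expect_equal(full$coefficients[names(truth)], truth, tolerance = 1e-6)
  absent <- setdiff(names(full$coefficients), names(truth))
  expect_true(all(abs(full$coefficients[absent]) < 1e-4))
})

test_that("degenerate fits fail loudly", {
  sp <- default_factor_space()
  g <- enumerate_grid(sp)
  design <- as_design(g[1:10, ], sp)
  y <- seq_len(10) * 100
  expect_error(fit_model(response_table(design$runs$run_id, y), design,
                         full_model_spec()),
               "underdetermined")
  # a solvent level never observed leaves an all-zero dummy column
  chl <- as_design(g[g$ext_solvent == "chloroform", ], sp)
  ych <- seq_len(nrow(chl$runs)) + 100
  expect_error(fit_model(response_table(chl$runs$run_id, ych), chl,
                         model_spec(c("ext_solvent", "ext_volume"))),
               "collinear")
  # all-non-detect analytes are unmodellable
  nd <- response_table(design$runs$run_id, y)
  nd$non_detect <- TRUE
  nd$peak_area <- NA_real_
  expect_error(fit_model(nd, design, model_spec("ext_volume")),
               "non-detects")
})

test_that("partial-F p-value of a single-column term squares the t-test", {
  sp <- toy_quant_space(c(1, 2, 3, 4, 5, 6, 7, 8))
  design <- full_grid_design(sp)
  set.seed(42)
  y <- 10 + 0.5 * design$runs$ext_volume_ul + rnorm(8)
  fit <- fit_model(response_table(design$runs$run_id, y), design,
                   model_spec("ext_volume"))
  tstat <- fit$coefficients["ext_volume_ul"] / fit$std_errors["ext_volume_ul"]
  p_t <- 2 * pt(-abs(tstat), df = fit$df_residual)
  expect_equal(unname(fit$term_pvalues["ext_volume"]), unname(p_t),
               tolerance = 1e-12)
})

test_that("elimination is monotone, idempotent and a fixed point when all
           terms are significant", {
  sp <- default_factor_space()
  design <- full_grid_design(sp)
  tr <- ethyl_octanoate_truth(noise_cv = 0.02)
  cfg <- synthetic_config(seed = 8, n_replicates = 1, noise_cv = 0.02)
  resp <- generate_design_responses(design, tr, cfg)
  fit <- fit_model(resp, design, full_model_spec())
  red <- backward_eliminate(fit)
  # monotone: retained terms are a subset of the starting terms
  expect_true(all(as.character(red$spec) %in% as.character(fit$spec)))
  # the four true terms always survive under this low noise
  expect_true(all(eo_terms() %in% as.character(red$spec)))
  # idempotent: re-eliminating changes nothing, and refitting the reduced
  # spec reproduces its own coefficients
  red2 <- backward_eliminate(red)
  expect_identical(as.character(red2$spec), as.character(red$spec))
  refit <- fit_model(resp, design, model_spec(as.character(red$spec)))
  expect_equal(refit$coefficients, red$coefficients, tolerance = 1e-10)
  # all surviving terms are significant
  expect_true(all(red$term_pvalues < 0.05))
})

test_that("weak heredity protects main effects of retained interactions", {
  sp <- factor_space(c("A", "B"), c(1, 2, 3, 4), "x", 1)
  design <- full_grid_design(sp)
  tr <- ground_truth_model(
    "interaction only",
    c("(Intercept)" = 10, "ext_solventB:ext_volume_ul" = 2))
  y <- truth_predict(tr, design$runs, sp)
  spec <- model_spec(c("ext_solvent", "ext_volume",
                       "ext_solvent:ext_volume"))
  fit <- fit_model(response_table(design$runs$run_id, y), design, spec)
  kept <- backward_eliminate(fit, heredity = TRUE)
  expect_setequal(as.character(kept$spec),
                  c("ext_solvent", "ext_volume", "ext_solvent:ext_volume"))
  pruned <- backward_eliminate(fit, heredity = FALSE)
  expect_identical(as.character(pruned$spec), "ext_solvent:ext_volume")
})

test_that("non-detect rows are excluded from the fit, not imputed", {
  sp <- default_factor_space()
  fx <- eo_noiseless_responses(sp)
  resp <- fx$responses
  pentane <- fx$design$runs$ext_solvent[match(resp$run_id,
                                              fx$design$runs$run_id)] ==
    "pentane"
  # corrupt pentane areas and mark them non-detect: the fit must ignore them,
  # but chloroform-reference terms are still estimable
  resp$peak_area[pentane] <- 0
  resp$non_detect[pentane] <- TRUE
  spec <- model_spec(c("ext_volume", "disp_solvent"))
  fit <- fit_model(resp, fx$design, spec)
  expect_equal(fit$n_obs, sum(!pentane))
})
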