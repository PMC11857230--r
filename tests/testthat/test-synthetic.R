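test_that("noiseless generator is an exact evaluator of the truth", {
  sp <- default_factor_space()
  tr <- ethyl_octanoate_truth()
  c1 <- data.frame(ext_solvent = "chloroform", ext_volume_ul = 2000,
                   disp_solvent = "acetonitrile", disp_volume_ul = 1000)
  expect_equal(truth_predict(tr, c1, sp), 100783)
  c2 <- data.frame(ext_solvent = "pentane", ext_volume_ul = 500,
                   disp_solvent = "acetone", disp_volume_ul = 500)
  expect_equal(truth_predict(tr, c2, sp), 186838)

  design <- full_grid_design(sp)
  cfg <- synthetic_config(seed = 3, n_replicates = 1, noise_cv = 0)
  resp <- generate_design_responses(design, tr, cfg)
  expect_equal(resp$peak_area, truth_predict(tr, design$runs, sp))
  expect_false(any(resp$non_detect))
})

test_that("failing solvents yield deterministic non-detects", {
  sp <- default_factor_space()
  tr <- ethyl_octanoate_truth(noise_cv = 0.05, failing_solvents = "pentane")
  design <- full_grid_design(sp)
  cfg <- synthetic_config(seed = 3, n_replicates = 2, noise_cv = 0.05)
  resp <- generate_design_responses(design, tr, cfg)
  solvent <- design$runs$ext_solvent[match(resp$run_id, design$runs$run_id)]
  expect_true(all(resp$non_detect[solvent == "pentane"]))
  expect_true(all(is.na(resp$peak_area[solvent == "pentane"])))
  expect_false(any(resp$non_detect[solvent != "pentane"]))
})

test_that("generation is seed-deterministic and noise-only across seeds", {
  sp <- default_factor_space()
  design <- full_grid_design(sp)
  tr <- ethyl_octanoate_truth(noise_cv = 0.05)
  r1 <- generate_design_responses(design, tr, synthetic_config(seed = 11,
                                                               noise_cv = 0.05))
  r2 <- generate_design_responses(design, tr, synthetic_config(seed = 11,
                                                               noise_cv = 0.05))
  r3 <- generate_design_responses(design, tr, synthetic_config(seed = 12,
                                                               noise_cv = 0.05))
  expect_identical(r1, r2)
  expect_false(identical(r1$peak_area, r3$peak_area))
  expect_identical(r1[, c("run_id", "replicate", "analyte")],
                   r3[, c("run_id", "replicate", "analyte")])
})

test_that("replicate RSD converges to the configured CV", {
  sp <- default_factor_space()
  one <- as_design(enumerate_grid(sp)[1, ], sp)
  tr <- ethyl_octanoate_truth(noise_cv = 0.05)
  cfg <- synthetic_config(seed = 21, n_replicates = 1000, noise_cv = 0.05)
  resp <- generate_design_responses(one, tr, cfg)
  rsd <- sd(resp$peak_area) / mean(resp$peak_area) * 100
  expect_equal(rsd, 5, tolerance = 0.1)
})

test_that("calibration series generator matches its closed form", {
  noiseless <- generate_calibration_samples(slope = 2, intercept = 0,
                                            sigma = 0, levels = c(1, 2, 3),
                                            n_duplicates = 1)
  expect_equal(noiseless$area_ratio, c(2, 4, 6))

  series <- generate_calibration_samples(2, 0.1, 0.6,
                                         levels = c(5, 10, 50, 100, 500, 1000),
                                         n_duplicates = 2, seed = 2)
  expect_equal(nrow(series), 12)
  expect_equal(attr(series, "true_slope"), 2)
  # downstream LOD closed form for the true parameters: 3.3 * 0.6 / 2
  expect_equal(unname(lod_loq(attr(series, "true_sigma"),
                              attr(series, "true_slope"))["LOD"]), 0.99)

  expect_error(generate_calibration_samples(2, 0, 0, levels = c(1, 5)),
               "3 distinct")
})

test_that("matrix study encodes the recovery factor exactly at zero noise", {
  base <- c("hexanal" = 50, "linalool" = 5)
  spikes <- c(low = 20, high = 100)
  s1 <- generate_matrix_study(base, spikes, matrix_effect_factor = 1,
                              noise_cv = 0, n_replicates = 3, seed = 1)
  rep1 <- recovery_report(s1)
  expect_equal(rep1$recovery_pct, rep(100, nrow(rep1)))

  s2 <- generate_matrix_study(base, spikes, matrix_effect_factor = 0.9,
                              noise_cv = 0, n_replicates = 3, seed = 1)
  rep2 <- recovery_report(s2)
  expect_equal(rep2$recovery_pct, rep(90, nrow(rep2)))

  # with mild noise, recoveries stay in the 80-120% acceptance band
  s3 <- generate_matrix_study(base, spikes, matrix_effect_factor = 1,
                              noise_cv = 0.03, n_replicates = 3, seed = 7)
  rep3 <- recovery_report(s3)
  expect_true(all(rep3$recovery_pct > 80 & rep3$recovery_pct < 120))
  expect_true(all(rep3$spiked_rsd < 10))
})

test_that("default truth panel has the expected structure", {
  truths <- default_ground_truths(seed = 5)
  expect_length(truths, 36)
  expect_named(truths, default_analytes())
  nd <- c("trans-2-hexen-1-ol", "beta-citronellol", "geraniol")
  for (a in nd) {
    expect_setequal(truths[[a]]$failing_solvents,
                    default_factor_space()$ext_solvents)
  }
  expect_equal(truths[["hexanal"]]$failing_solvents, "pentane")
  expect_identical(default_ground_truths(seed = 5)[["hexanal"]]$coefficients,
                   truths[["hexanal"]]$coefficients)
})
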