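# shared toy fixtures; everything is built in code at test time

# one-dimensional quantitative space: a single solvent at each categorical
# factor, ext_volume carrying the signal
toy_quant_space <- function(volumes = c(1, 2, 3, 4)) {
  factor_space(ext_solvents = "solv", ext_volumes = volumes,
               disp_solvents = "disp", disp_volumes = 1)
}

toy_conditions <- function(volumes, space) {
  data.frame(ext_solvent = space$ext_solvents[1], ext_volume_ul = volumes,
             disp_solvent = space$disp_solvents[1],
             disp_volume_ul = space$disp_volumes[1],
             stringsAsFactors = FALSE)
}

# design over the full 225-condition grid (used for noiseless oracle fits)
full_grid_design <- function(space = default_factor_space()) {
  as_design(enumerate_grid(space), space)
}

# single-analyte response table from explicit conditions and y values
response_table <- function(run_id, y, analyte = "test analyte") {
  data.frame(run_id = run_id, analyte = analyte, peak_area = y,
             area_ratio = y / 1e5, non_detect = FALSE,
             stringsAsFactors = FALSE)
}

# the reduced ethyl octanoate term set
eo_terms <- function() {
  c("ext_solvent", "ext_volume", "disp_solvent", "ext_solvent:ext_volume")
}

# noiseless responses of the packaged ethyl octanoate truth over the grid
eo_noiseless_responses <- function(space = default_factor_space()) {
  design <- full_grid_design(space)
  y <- truth_predict(ethyl_octanoate_truth(), design$runs, space)
  list(design = design,
       responses = response_table(design$runs$run_id, y, "ethyl octanoate"))
}

# hand-rolled prediction_grid for ranking tests: `values` is a
# conditions x analytes matrix
manual_grid <- function(values, space) {
  conditions <- enumerate_grid(space)
  stopifnot(nrow(conditions) == nrow(values))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("analyte", seq_len(ncol(values)))
  }
  structure(list(conditions = conditions, predicted = pmax(values, 0),
                 raw = values, clamped = values < 0,
                 analytes = colnames(values)),
            class = "prediction_grid")
}

# independent competition-ranking oracle: condition is in an analyte's top-m
# iff fewer than m conditions beat it strictly
brute_top_m_counts <- function(values, top_m) {
  counts <- integer(nrow(values))
  for (a in seq_len(ncol(values))) {
    for (i in seq_len(nrow(values))) {
      n_better <- sum(values[, a] > values[i, a])
      if (n_better < top_m) counts[i] <- counts[i] + 1L
    }
  }
  counts
}
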