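#' Response-surface model terms
#'
#' The regression of extraction response on the four DLLME factors uses terms
#' drawn from a fixed vocabulary: main effects of the two categorical solvent
#' types and the two quantitative volumes, quadratic volume terms, and the
#' two-factor interactions solvent-type x volume (same phase) and extraction
#' solvent x disperser solvent. Quantitative factors enter in raw microlitres;
#' categorical factors are treatment-coded against the factor-space reference
#' levels.
#'
#' @param terms Character vector of term codes, a subset of
#'   `all_model_terms()`. The intercept is always included and need not be
#'   listed.
#' @return An object of class `model_spec` (a character vector of terms).
#' @export
model_spec <- function(terms) {
  terms <- setdiff(as.character(terms), "intercept")
  unknown <- setdiff(terms, all_model_terms())
  if (length(unknown)) {
    stop("unknown model term(s): ", paste(unknown, collapse = ", "),
         "; valid terms are ", paste(all_model_terms(), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(terms)) stop("duplicate model terms", call. = FALSE)
  # keep canonical ordering so column layout is stable
  terms <- all_model_terms()[all_model_terms() %in% terms]
  structure(terms, class = "model_spec")
}

#' @rdname model_spec
#' @export
all_model_terms <- function() {
  c("ext_solvent", "ext_volume", "ext_volume^2",
    "disp_solvent", "disp_volume", "disp_volume^2",
    "ext_solvent:ext_volume", "disp_solvent:disp_volume",
    "ext_solvent:disp_solvent")
}

#' @rdname model_spec
#' @export
full_model_spec <- function() model_spec(all_model_terms())

# factors entering a term, used for heredity during backward elimination
term_factors <- function(term) {
  switch(term,
    "ext_solvent" = "ext_solvent",
    "ext_volume" = "ext_volume",
    "ext_volume^2" = "ext_volume",
    "disp_solvent" = "disp_solvent",
    "disp_volume" = "disp_volume",
    "disp_volume^2" = "disp_volume",
    "ext_solvent:ext_volume" = c("ext_solvent", "ext_volume"),
    "disp_solvent:disp_volume" = c("disp_solvent", "disp_volume"),
    "ext_solvent:disp_solvent" = c("ext_solvent", "disp_solvent"),
    stop("unknown term: ", term, call. = FALSE)
  )
}

is_compound_term <- function(term) {
  grepl(":", term, fixed = TRUE) || grepl("^", term, fixed = TRUE)
}

# indicator-column labels for the non-reference levels; empty when a factor
# has a single level (paste0 would otherwise emit the bare prefix)
dummy_labels <- function(prefix, levels, ref) {
  paste0(prefix, setdiff(levels, ref), recycle0 = TRUE)
}

# column labels of one term's expansion on a given space
term_columns <- function(term, space) {
  ext_dummies <- dummy_labels("ext_solvent", space$ext_solvents,
                              space$ref_ext)
  disp_dummies <- dummy_labels("disp_solvent", space$disp_solvents,
                               space$ref_disp)
  switch(term,
    "ext_solvent" = ext_dummies,
    "ext_volume" = "ext_volume_ul",
    "ext_volume^2" = "ext_volume_ul_sq",
    "disp_solvent" = disp_dummies,
    "disp_volume" = "disp_volume_ul",
    "disp_volume^2" = "disp_volume_ul_sq",
    "ext_solvent:ext_volume" = paste0(ext_dummies, ":ext_volume_ul",
                                      recycle0 = TRUE),
    "disp_solvent:disp_volume" = paste0(disp_dummies, ":disp_volume_ul",
                                        recycle0 = TRUE),
    "ext_solvent:disp_solvent" = {
      labs <- character(0)
      for (e in ext_dummies) for (d in disp_dummies) {
        labs <- c(labs, paste0(e, ":", d))
      }
      labs
    },
    stop("unknown term: ", term, call. = FALSE)
  )
}

#' Build the regression model matrix for a set of conditions
#'
#' Expands conditions into a numeric model matrix under the package's coding:
#' treatment-coded indicator columns for the solvent types (relative to the
#' factor-space reference levels), raw µL values for the volumes, squared raw
#' values for quadratic terms, and elementwise products for interactions.
#' Column labels are deterministic and stable across calls.
#'
#' @param conditions Data.frame of conditions (see [enumerate_grid()]).
#' @param spec A [model_spec()].
#' @param space The [factor_space()] the conditions live in.
#' @return A numeric matrix with one row per condition; the first column is
#'   the intercept.
#' @export
model_matrix <- function(conditions, spec, space) {
  stopifnot(inherits(space, "factor_space"))
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  check_conditions(conditions, space)
  n <- nrow(conditions)

  base_cols <- list("(Intercept)" = rep(1, n))
  for (lev in setdiff(space$ext_solvents, space$ref_ext)) {
    base_cols[[paste0("ext_solvent", lev)]] <-
      as.numeric(conditions$ext_solvent == lev)
  }
  for (lev in setdiff(space$disp_solvents, space$ref_disp)) {
    base_cols[[paste0("disp_solvent", lev)]] <-
      as.numeric(conditions$disp_solvent == lev)
  }
  base_cols[["ext_volume_ul"]] <- as.numeric(conditions$ext_volume_ul)
  base_cols[["disp_volume_ul"]] <- as.numeric(conditions$disp_volume_ul)
  base_cols[["ext_volume_ul_sq"]] <- base_cols[["ext_volume_ul"]]^2
  base_cols[["disp_volume_ul_sq"]] <- base_cols[["disp_volume_ul"]]^2

  ext_dummies <- dummy_labels("ext_solvent", space$ext_solvents,
                              space$ref_ext)
  disp_dummies <- dummy_labels("disp_solvent", space$disp_solvents,
                               space$ref_disp)
  # columns built structurally per term (solvent labels may themselves
  # contain ':', so interaction labels are never parsed back apart)
  term_cols <- function(term) {
    switch(term,
      "ext_solvent" = base_cols[ext_dummies],
      "ext_volume" = base_cols["ext_volume_ul"],
      "ext_volume^2" = base_cols["ext_volume_ul_sq"],
      "disp_solvent" = base_cols[disp_dummies],
      "disp_volume" = base_cols["disp_volume_ul"],
      "disp_volume^2" = base_cols["disp_volume_ul_sq"],
      "ext_solvent:ext_volume" = lapply(base_cols[ext_dummies],
                                        `*`, base_cols[["ext_volume_ul"]]),
      "disp_solvent:disp_volume" = lapply(base_cols[disp_dummies],
                                          `*`,
                                          base_cols[["disp_volume_ul"]]),
      "ext_solvent:disp_solvent" = {
        out <- list()
        for (e in ext_dummies) for (d in disp_dummies) {
          out[[paste0(e, ":", d)]] <- base_cols[[e]] * base_cols[[d]]
        }
        out
      },
      stop("unknown term: ", term, call. = FALSE)
    )
  }
  cols <- c(list("(Intercept)" = base_cols[["(Intercept)"]]),
            unlist(lapply(spec, term_cols), recursive = FALSE))
  labels <- c("(Intercept)", unlist(lapply(spec, term_columns, space = space),
                                    use.names = FALSE))
  X <- do.call(cbind, unname(cols))
  colnames(X) <- labels
  X
}

#' D-optimality criterion of a candidate design
#'
#' Computes det(X'X) for the model matrix X of the given runs. The value is
#' invariant to run ordering; a rank-deficient design returns 0.
#'
#' @param conditions Data.frame of design runs.
#' @param spec A [model_spec()].
#' @param space A [factor_space()].
#' @return A non-negative scalar.
#' @export
d_criterion <- function(conditions, spec, space) {
  X <- model_matrix(conditions, spec, space)
  if (nrow(X) < ncol(X)) return(0)
  if (qr(X)$rank < ncol(X)) return(0)
  det(crossprod(X))
}
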