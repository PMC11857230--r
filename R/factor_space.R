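#' Define a DLLME factor space
#'
#' A factor space holds the levels of the four experimental variables of a
#' dispersive liquid-liquid microextraction (DLLME) optimisation: extraction
#' solvent type, extraction solvent volume, disperser solvent type and
#' disperser solvent volume. Categorical factors carry a reference level used
#' for treatment (dummy) coding of model matrices.
#'
#' @param ext_solvents Character vector of extraction-solvent labels.
#' @param ext_volumes Numeric vector of extraction-solvent volumes (µL),
#'   strictly increasing and positive.
#' @param disp_solvents Character vector of disperser-solvent labels.
#' @param disp_volumes Numeric vector of disperser volumes (µL), strictly
#'   increasing and positive.
#' @param ref_ext Reference extraction solvent (default: first level).
#' @param ref_disp Reference disperser solvent (default: first level).
#'
#' @return An object of class `factor_space`.
#' @seealso [default_factor_space()] for the standard wine-aroma study space,
#'   [enumerate_grid()], [model_matrix()].
#' @export
factor_space <- function(ext_solvents, ext_volumes, disp_solvents,
                         disp_volumes, ref_ext = ext_solvents[1],
                         ref_disp = disp_solvents[1]) {
  ext_solvents <- as.character(ext_solvents)
  disp_solvents <- as.character(disp_solvents)
  ext_volumes <- as.numeric(ext_volumes)
  disp_volumes <- as.numeric(disp_volumes)
  if (length(ext_solvents) < 1L || length(disp_solvents) < 1L ||
      length(ext_volumes) < 1L || length(disp_volumes) < 1L) {
    stop("factor space unusable: every factor needs at least one level",
         call. = FALSE)
  }
  if (anyDuplicated(ext_solvents) || anyDuplicated(disp_solvents)) {
    stop("solvent labels must be unique", call. = FALSE)
  }
  for (v in list(ext_volumes, disp_volumes)) {
    if (any(v <= 0) || is.unsorted(v, strictly = TRUE)) {
      stop("volumes must be strictly positive and strictly increasing",
           call. = FALSE)
    }
  }
  if (!ref_ext %in% ext_solvents) {
    stop("reference extraction solvent '", ref_ext,
         "' is not a level of the factor space", call. = FALSE)
  }
  if (!ref_disp %in% disp_solvents) {
    stop("reference disperser solvent '", ref_disp,
         "' is not a level of the factor space", call. = FALSE)
  }
  structure(
    list(ext_solvents = ext_solvents, ext_volumes = ext_volumes,
         disp_solvents = disp_solvents, disp_volumes = disp_volumes,
         ref_ext = ref_ext, ref_disp = ref_disp),
    class = "factor_space"
  )
}

#' The standard wine-aroma DLLME factor space
#'
#' Five extraction solvents (chloroform, dichloromethane, hexane, pentane and
#' a 2:1 chloroform/pentane mixture), five extraction volumes (500--2000 µL),
#' three disperser solvents (acetone, acetonitrile, methanol) and three
#' disperser volumes (500--1500 µL): a 5 x 5 x 3 x 3 space of 225 candidate
#' conditions. Chloroform and acetone are the treatment-coding references.
#'
#' @return A `factor_space`.
#' @export
default_factor_space <- function() {
  factor_space(
    ext_solvents = c("chloroform", "DCM", "hexane", "pentane", "CH:P 2:1"),
    ext_volumes = c(500, 750, 1000, 1500, 2000),
    disp_solvents = c("acetone", "acetonitrile", "methanol"),
    disp_volumes = c(500, 1000, 1500),
    ref_ext = "chloroform",
    ref_disp = "acetone"
  )
}

#' @export
print.factor_space <- function(x, ...) {
  cat("DLLME factor space\n")
  cat("  extraction solvents:", paste(x$ext_solvents, collapse = ", "),
      sprintf("(ref: %s)\n", x$ref_ext))
  cat("  extraction volumes (uL):", paste(x$ext_volumes, collapse = ", "), "\n")
  cat("  disperser solvents:", paste(x$disp_solvents, collapse = ", "),
      sprintf("(ref: %s)\n", x$ref_disp))
  cat("  disperser volumes (uL):", paste(x$disp_volumes, collapse = ", "), "\n")
  invisible(x)
}

condition_columns <- c("ext_solvent", "ext_volume_ul",
                       "disp_solvent", "disp_volume_ul")

#' Enumerate the full candidate grid of a factor space
#'
#' Returns the Cartesian product of all factor levels in a fixed, deterministic
#' order: extraction solvent varies slowest, disperser volume fastest (nested
#' loops in factor order).
#'
#' @param space A [factor_space()].
#' @return A data.frame with columns `ext_solvent`, `ext_volume_ul`,
#'   `disp_solvent`, `disp_volume_ul`, one row per condition.
#' @export
enumerate_grid <- function(space) {
  stopifnot(inherits(space, "factor_space"))
  g <- expand.grid(
    disp_volume_ul = space$disp_volumes,
    disp_solvent = space$disp_solvents,
    ext_volume_ul = space$ext_volumes,
    ext_solvent = space$ext_solvents,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[, condition_columns]
  rownames(g) <- NULL
  g
}

# validate condition rows against a space; errors name the offending level
check_conditions <- function(conditions, space) {
  if (!is.data.frame(conditions) ||
      !all(condition_columns %in% names(conditions))) {
    stop("conditions must be a data.frame with columns ",
         paste(condition_columns, collapse = ", "), call. = FALSE)
  }
  bad_ext <- setdiff(unique(conditions$ext_solvent), space$ext_solvents)
  if (length(bad_ext)) {
    stop("extraction solvent level not in factor space: ",
         paste(bad_ext, collapse = ", "), call. = FALSE)
  }
  bad_disp <- setdiff(unique(conditions$disp_solvent), space$disp_solvents)
  if (length(bad_disp)) {
    stop("disperser solvent level not in factor space: ",
         paste(bad_disp, collapse = ", "), call. = FALSE)
  }
  bad_ev <- setdiff(unique(conditions$ext_volume_ul), space$ext_volumes)
  if (length(bad_ev)) {
    stop("extraction volume not in factor space: ",
         paste(bad_ev, collapse = ", "), call. = FALSE)
  }
  bad_dv <- setdiff(unique(conditions$disp_volume_ul), space$disp_volumes)
  if (length(bad_dv)) {
    stop("disperser volume not in factor space: ",
         paste(bad_dv, collapse = ", "), call. = FALSE)
  }
  invisible(conditions)
}
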