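#' The probing grid
#'
#' Crosses short/average/long axial lengths with low/average/high mean
#' keratometry. Each cell becomes one test eye: the mean K is split into
#' flat/steep readings `mean_k -/+ test_cylinder/2` at `steep_axis`, with
#' zero SIA and a plano target.
#'
#' @param axial_lengths strictly increasing axial lengths in mm
#'   (default 21, 24, 27 mm).
#' @param mean_ks strictly increasing mean keratometries in diopters
#'   (default 39, 43, 47 D).
#' @param test_cylinder corneal cylinder of the probe eyes in diopters
#'   (default 4.00 D; higher cylinders resolve the ratio with less display
#'   rounding error).
#' @param steep_axis steep axis in degrees (default 90; the extracted ratio
#'   is axis-invariant).
#' @return An object of class `probe_grid`.
#' @export
probe_grid <- function(axial_lengths = c(21, 24, 27),
                       mean_ks = c(39, 43, 47),
                       test_cylinder = 4, steep_axis = 90) {
  if (length(axial_lengths) < 1 || is.unsorted(axial_lengths, strictly = TRUE))
    stop_toricity("axial_lengths must be strictly increasing", "toricity_invalid")
  if (length(mean_ks) < 1 || is.unsorted(mean_ks, strictly = TRUE))
    stop_toricity("mean_ks must be strictly increasing", "toricity_invalid")
  if (test_cylinder <= 0)
    stop_toricity("test_cylinder must be > 0", "toricity_invalid")
  structure(list(axial_lengths = axial_lengths, mean_ks = mean_ks,
                 test_cylinder = test_cylinder,
                 steep_axis = norm_axis(steep_axis)),
            class = "probe_grid")
}

grid_case <- function(grid, al, mk) {
  biometry_case(al, mk - grid$test_cylinder / 2, mk + grid$test_cylinder / 2,
                steep_axis = grid$steep_axis, sia = cyl(0, 0),
                target_refraction = 0)
}

#' Build the per-cell probe cases
#'
#' One biometry case per (axial length, mean K) cell, plus the SRK/T-inverted
#' sphere power that would be typed into the calculator.
#'
#' @param grid a [probe_grid()].
#' @param constants an [iol_constants()] used for the sphere inversion.
#' @return A data frame with one row per cell: `axial_length_mm`,
#'   `mean_k_D`, `k_flat_D`, `k_steep_D`, `steep_axis_deg`, `sphere_D`.
#' @examples
#' build_cases(probe_grid(), iol_constants(118.8))
#' @export
build_cases <- function(grid, constants) {
  stopifnot(inherits(grid, "probe_grid"))
  cells <- expand.grid(mean_k_D = grid$mean_ks,
                       axial_length_mm = grid$axial_lengths)
  sphere <- vapply(seq_len(nrow(cells)), function(i) {
    as.numeric(invert_for_target(
      grid_case(grid, cells$axial_length_mm[i], cells$mean_k_D[i]), constants))
  }, numeric(1))
  data.frame(axial_length_mm = cells$axial_length_mm,
             mean_k_D = cells$mean_k_D,
             k_flat_D = cells$mean_k_D - grid$test_cylinder / 2,
             k_steep_D = cells$mean_k_D + grid$test_cylinder / 2,
             steep_axis_deg = grid$steep_axis,
             sphere_D = sphere)
}

#' Probe a calculator and assemble the toricity matrix
#'
#' For every grid cell, queries the calculator with the cell's biometry,
#' takes the recommended lens with the smallest residual astigmatism, signs
#' the residual against the cross-cylinder axis, extracts the toricity ratio
#' and fills the matrix. A cell where extraction fails (oblique residual
#' axis, or residual at least as large as the attempted correction) is
#' marked invalid with its reason recorded; the matrix is still returned.
#'
#' @param calculator a function of a [biometry_case()] returning the
#'   calculator's printable output: a data frame with columns `name`,
#'   `cylinder_iol_plane_D`, `residual_D`, `residual_axis_deg`. See
#'   [simulated_calculator()] and [transcript_calculator()].
#' @param grid a [probe_grid()].
#' @param tolerance classification tolerance on max - min of the extracted
#'   ratios (default 0.02, one unit in the second printed decimal on each
#'   side).
#' @return A [toricity_matrix()].
#' @examples
#' calc <- simulated_calculator(default_catalog("alcon_acrysof"),
#'                              toricity_model("constant", constant_value = 1.46))
#' probe(calc)
#' @export
probe <- function(calculator, grid = probe_grid(), tolerance = 0.02) {
  stopifnot(is.function(calculator), inherits(grid, "probe_grid"))
  cells <- expand.grid(mean_k_D = grid$mean_ks,
                       axial_length_mm = grid$axial_lengths)
  prov <- vector("list", nrow(cells))
  vals <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    al <- cells$axial_length_mm[i]; mk <- cells$mean_k_D[i]
    case <- grid_case(grid, al, mk)
    cc <- cross_cylinder(
      corneal_cylinder(case$k_steep, case$k_flat, case$steep_axis), case$sia)
    row <- data.frame(axial_length_mm = al, mean_k_D = mk,
                      lens = NA_character_, lens_cyl_D = NA_real_,
                      residual_D = NA_real_, residual_axis_deg = NA_real_,
                      tau = NA_real_, valid = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
    ans <- tryCatch({
      rec <- calculator(case)
      if (is.null(rec) || nrow(rec) == 0)
        stop_toricity("calculator returned no recommendation", "toricity_empty")
      # protocol rule: the lens predicting the smallest residual astigmatism
      best <- rec[order(rec$residual_D, rec$cylinder_iol_plane_D), , drop = FALSE][1, ]
      tr <- extract_toricity(best$cylinder_iol_plane_D, cc, best$residual_D,
                             residual_axis = best$residual_axis_deg)
      row$lens <- best$name; row$lens_cyl_D <- best$cylinder_iol_plane_D
      row$residual_D <- best$residual_D
      row$residual_axis_deg <- best$residual_axis_deg
      row$tau <- tr$value; row$valid <- TRUE
      row
    }, toricity_error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
    prov[[i]] <- ans
    vals[i] <- ans$tau
  }
  provenance <- do.call(rbind, prov)
  # matrix orientation: mean K descending down the rows, AL ascending across
  values <- matrix(NA_real_, nrow = length(grid$mean_ks),
                   ncol = length(grid$axial_lengths),
                   dimnames = list(rev(as.character(grid$mean_ks)),
                                   as.character(grid$axial_lengths)))
  for (i in seq_len(nrow(cells))) {
    values[as.character(cells$mean_k_D[i]),
           as.character(cells$axial_length_mm[i])] <- vals[i]
  }
  toricity_matrix(values, provenance = provenance, tolerance = tolerance,
                  grid = grid)
}

#' A probed matrix of toricity ratios
#'
#' @param values numeric matrix of extracted ratios, rows = mean K
#'   *descending*, columns = axial length *ascending* (row/column names are
#'   the numeric axis values); `NA` marks an invalid cell.
#' @param provenance optional per-cell data frame (lens used, residual used,
#'   validity, failure reason).
#' @param tolerance classification tolerance (see [classify()]).
#' @param grid the [probe_grid()] that produced the matrix, if any.
#' @return An object of class `toricity_matrix` with the classification
#'   (`"constant"`, `"variable"` or `"indeterminate"`) and, when constant,
#'   the `constant_value` (median of the valid cells).
#' @export
toricity_matrix <- function(values, provenance = NULL, tolerance = 0.02,
                            grid = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_toricity("toricity matrix needs mean-K row names and AL column names",
                  "toricity_invalid")
  cls <- classify(values, tolerance = tolerance)
  structure(list(values = values, provenance = provenance,
                 classification = cls$classification,
                 constant_value = cls$constant_value,
                 tolerance = tolerance, grid = grid),
            class = "toricity_matrix")
}

#' Classify a toricity matrix as constant or variable
#'
#' A calculator is called *constant-ratio* when the spread (max - min) of
#' the valid extracted ratios does not exceed `tolerance`; the constant is
#' then the median cell. Fewer than two valid cells cannot distinguish the
#' two and is `"indeterminate"`.
#'
#' @param x a `toricity_matrix` or a bare numeric matrix of ratios.
#' @param tolerance maximal spread still called constant (default 0.02,
#'   which absorbs display rounding of the second decimal).
#' @return `list(classification = "constant"|"variable"|"indeterminate",
#'   constant_value = median or NA)`.
#' @export
classify <- function(x, tolerance = 0.02) {
  values <- if (inherits(x, "toricity_matrix")) x$values else as.matrix(x)
  v <- values[is.finite(values)]
  if (length(v) < 2)
    return(list(classification = "indeterminate", constant_value = NA_real_))
  if (max(v) - min(v) <= tolerance + 1e-12)
    list(classification = "constant", constant_value = stats::median(v))
  else
    list(classification = "variable", constant_value = NA_real_)
}

#' @export
print.toricity_matrix <- function(x, digits = 2, ...) {
  cat("Toricity ratio matrix (rows: mean K [D] desc; cols: AL [mm] asc)\n")
  shown <- round_half_up(x$values, digits)
  print(shown, na.print = "NA")
  if (x$classification == "constant")
    cat(sprintf("classification: constant (ratio %.2f, tolerance %.2f)\n",
                x$constant_value, x$tolerance))
  else
    cat(sprintf("classification: %s (tolerance %.2f)\n", x$classification,
                x$tolerance))
  invisible(x)
}
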