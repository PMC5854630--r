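#' Sign a calculator's residual astigmatism
#'
#' A toric calculator prints the residual astigmatism as a magnitude and an
#' axis. By convention the residual is *positive* (under-correction) when its
#' axis coincides with the axis of the astigmatism being corrected, and
#' *negative* (over-correction) when the axis has flipped 90 degrees. Axes
#' are compared modulo 180 with a +/- `tol` window; a residual oblique to
#' both windows cannot be signed by scalar arithmetic and is an error.
#'
#' @param residual_magnitude printed residual magnitude in diopters (>= 0).
#' @param residual_axis printed residual axis in degrees.
#' @param corneal_steep_axis axis of the corrected (cross-cylinder)
#'   astigmatism in degrees.
#' @param tol axis tolerance in degrees (default 5).
#' @return Signed residual in diopters; a zero magnitude is 0 regardless of
#'   axes.
#' @examples
#' signed_residual(0.40, 90, 90)  # +0.40, under-correction
#' signed_residual(0.50,  0, 90)  # -0.50, axis flipped: over-correction
#' @export
signed_residual <- function(residual_magnitude, residual_axis,
                            corneal_steep_axis, tol = 5) {
  if (residual_magnitude < 0)
    stop_toricity("residual magnitude must be >= 0", "toricity_invalid")
  if (residual_magnitude == 0) return(0)
  d <- axis_distance(residual_axis, corneal_steep_axis)
  if (d <= tol) return(residual_magnitude)
  if (abs(d - 90) <= tol) return(-residual_magnitude)
  stop_toricity(
    sprintf("oblique residual axis (%g° off the corrected axis) - vector extraction required",
            d),
    "toricity_oblique_axis")
}

#' Extract the toricity ratio from a calculator's printed output
#'
#' The core identity: a calculator that attempts to correct a cross cylinder
#' \eqn{C_c} with a lens of cylinder \eqn{L_c} at the IOL plane, using
#' toricity ratio \eqn{\tau}, leaves residual \eqn{r = C_c - L_c/\tau}.
#' Solving for the ratio,
#' \deqn{\tau = L_c / (C_c - r),}
#' so the ratio is recoverable from printed inputs and outputs alone,
#' with `C_c - r` the lens's effective toricity at the corneal plane.
#'
#' @param lens_cyl lens cylinder power at the IOL plane, diopters (> 0).
#' @param cross_cyl the astigmatism being corrected: either a [cyl()]
#'   (magnitude + axis, e.g. from [cross_cylinder()]) or a bare magnitude in
#'   diopters. With zero SIA this is simply the corneal cylinder.
#' @param residual the calculator's residual astigmatism magnitude
#'   (diopters). If `residual_axis` is `NULL`, `residual` is taken as
#'   already signed; otherwise the sign is derived from the axes via
#'   [signed_residual()].
#' @param residual_axis printed residual axis in degrees, or `NULL`.
#' @param axis_tol axis-matching tolerance in degrees (default 5).
#' @return An object of class `toricity_ratio` with fields `value` (full
#'   precision), `display` (two decimals, as calculators and tables print),
#'   `corneal_plane_toricity` (`C_c - r`, diopters), `lens_cylinder`, and
#'   `signed_residual`.
#' @examples
#' extract_toricity(5.25, cyl(4, 90), 0.40, residual_axis = 90)  # tau 1.46
#' extract_toricity(6.00, cyl(4, 90), 0.50, residual_axis = 0)   # tau 1.33
#' @export
extract_toricity <- function(lens_cyl, cross_cyl, residual,
                             residual_axis = NULL, axis_tol = 5) {
  if (!is.numeric(lens_cyl) || lens_cyl <= 0)
    stop_toricity("lens cylinder at the IOL plane must be > 0",
                  "toricity_invalid")
  cc <- as_cyl(cross_cyl, axis = 90)
  r <- if (is.null(residual_axis)) {
    residual
  } else {
    signed_residual(residual, residual_axis, cc$axis, tol = axis_tol)
  }
  denom <- cc$magnitude - r
  if (denom <= 0)
    stop_toricity("non-physical extraction: residual >= attempted correction",
                  "toricity_nonphysical")
  structure(list(value = lens_cyl / denom,
                 display = round_half_up(lens_cyl / denom, 2),
                 corneal_plane_toricity = denom,
                 lens_cylinder = lens_cyl,
                 signed_residual = r),
            class = "toricity_ratio")
}

#' @export
print.toricity_ratio <- function(x, ...) {
  cat(sprintf("toricity ratio %.2f  (lens %.2f D at IOL plane / %.2f D at corneal plane; residual %+.2f D)\n",
              x$display, x$lens_cylinder, x$corneal_plane_toricity,
              x$signed_residual))
  invisible(x)
}

#' Forward residual of a toric correction
#'
#' The forward counterpart of [extract_toricity()]:
#' `r = C_c - L_c / tau`. Positive means under-correction (residual at the
#' corrected axis); negative means over-correction (axis flips 90 degrees).
#'
#' @param lens_cyl lens cylinder at the IOL plane, diopters.
#' @param cross_cyl_magnitude magnitude of the astigmatism being corrected,
#'   diopters.
#' @param tau toricity ratio (> 0).
#' @return Signed residual astigmatism in diopters.
#' @export
predict_residual <- function(lens_cyl, cross_cyl_magnitude, tau) {
  if (!is.numeric(tau) || tau <= 0)
    stop_toricity("tau must be > 0", "toricity_invalid")
  cross_cyl_magnitude - lens_cyl / tau
}

#' Batch extraction over a data frame
#'
#' Applies [extract_toricity()] row-wise to a table with columns
#' `lens_cyl_D`, `cross_cyl_D`, `steep_axis_deg`, `residual_D`,
#' `residual_axis_deg` (the batch CSV schema of the `extract` subcommand).
#'
#' @param df a data.frame with the columns above.
#' @return `df` with `tau` and `corneal_plane_toricity_D` columns appended.
#' @export
batch_extract <- function(df) {
  need <- c("lens_cyl_D", "cross_cyl_D", "steep_axis_deg", "residual_D",
            "residual_axis_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_toricity(paste("batch extraction input lacks columns:",
                        paste(missing_cols, collapse = ", ")),
                  "toricity_invalid")
  res <- lapply(seq_len(nrow(df)), function(i) {
    extract_toricity(df$lens_cyl_D[i],
                     cyl(df$cross_cyl_D[i], df$steep_axis_deg[i]),
                     df$residual_D[i], residual_axis = df$residual_axis_deg[i])
  })
  df$tau <- round_half_up(vapply(res, `[[`, numeric(1), "value"), 2)
  df$corneal_plane_toricity_D <-
    vapply(res, `[[`, numeric(1), "corneal_plane_toricity")
  df
}
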