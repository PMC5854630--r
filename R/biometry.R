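#' One eye's biometry
#'
#' Bundles the inputs a toric IOL calculator asks for: axial length,
#' flat/steep keratometry with the steep axis, surgically induced astigmatism
#' and the refractive target.
#'
#' @param axial_length axial length in mm; sanity bounds 15--35
#'   (probing uses 21, 24, 27 for short/average/long eyes).
#' @param k_flat,k_steep flat and steep keratometry in diopters,
#'   `30 <= k_flat <= k_steep <= 60`.
#' @param steep_axis steep-meridian axis in degrees (default 90).
#' @param sia surgically induced astigmatism, a [cyl()] or 0 (default 0:
#'   SIA has no bearing on ratio extraction).
#' @param target_refraction desired postoperative spherical equivalent in
#'   diopters (default 0, plano).
#' @return An object of class `biometry_case`.
#' @examples
#' b <- biometry_case(21, 37, 41)
#' mean_k(b)  # 39
#' @export
biometry_case <- function(axial_length, k_flat, k_steep, steep_axis = 90,
                          sia = cyl(0, 0), target_refraction = 0) {
  stopifnot(is.numeric(axial_length), is.numeric(k_flat), is.numeric(k_steep),
            is.numeric(steep_axis), is.numeric(target_refraction))
  if (axial_length < 15 || axial_length > 35)
    stop_toricity("axial_length outside sanity bounds [15, 35] mm",
                  "toricity_invalid")
  if (k_flat < 30 || k_steep > 60 || k_flat > k_steep)
    stop_toricity("require 30 <= k_flat <= k_steep <= 60 D", "toricity_invalid")
  structure(list(axial_length = axial_length, k_flat = k_flat,
                 k_steep = k_steep, steep_axis = norm_axis(steep_axis),
                 sia = as_cyl(sia), target_refraction = target_refraction),
            class = "biometry_case")
}

#' @rdname biometry_case
#' @param case a `biometry_case`.
#' @export
mean_k <- function(case) (case$k_flat + case$k_steep) / 2

#' @export
print.biometry_case <- function(x, ...) {
  cat(sprintf("AL %.2f mm | K %.2f/%.2f @ %g° (mean %.2f D) | SIA %s | target %+.2f D\n",
              x$axial_length, x$k_flat, x$k_steep, x$steep_axis, mean_k(x),
              format(x$sia), x$target_refraction))
  invisible(x)
}

#' Lens-family constants for sphere power calculation
#'
#' @param a_constant SRK/T A-constant of the lens family (110--125); no
#'   constant is published for the probed calculators, so defaults are
#'   calibrated (see the shipped catalogs and the methods vignette).
#' @param rounding_step commercial power step in diopters (default 0.5).
#' @return An object of class `iol_constants`.
#' @export
iol_constants <- function(a_constant, rounding_step = 0.5) {
  stopifnot(is.numeric(a_constant), length(a_constant) == 1L)
  if (a_constant < 110 || a_constant > 125)
    stop_toricity("a_constant outside [110, 125]", "toricity_invalid")
  if (rounding_step <= 0)
    stop_toricity("rounding_step must be > 0", "toricity_invalid")
  structure(list(a_constant = a_constant, rounding_step = rounding_step),
            class = "iol_constants")
}
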