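#' Astigmatism (cylinder) vectors
#'
#' A cylinder is a magnitude in diopters plus an axis in degrees. Because an
#' axis is only defined modulo 180 degrees, cylinders do not add like plane
#' vectors: the standard construction maps a cylinder \eqn{(m, \theta)} to the
#' double-angle Cartesian point \eqn{(m\cos 2\theta, m\sin 2\theta)}, where
#' addition is componentwise, and maps back. Perpendicular cylinders of equal
#' magnitude cancel exactly in this representation.
#'
#' @param magnitude cylinder power in diopters, must be >= 0.
#' @param axis axis in degrees; reduced modulo 180 so that 185 becomes 5.
#'   A zero-magnitude cylinder has its (meaningless) axis normalized to 0.
#' @return An object of class `cyl` with fields `magnitude` and `axis`
#'   (axis in the half-open interval \[0, 180)).
#' @examples
#' cyl(4, 90)
#' add_cylinders(cyl(1, 0), cyl(1, 90))   # perpendicular equals cancel
#' @export
cyl <- function(magnitude, axis = 0) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L, is.finite(magnitude),
            is.numeric(axis), length(axis) == 1L, is.finite(axis))
  if (magnitude < 0)
    stop_toricity("cylinder magnitude must be >= 0", "toricity_invalid")
  axis <- if (magnitude == 0) 0 else norm_axis(axis)
  structure(list(magnitude = magnitude, axis = axis), class = "cyl")
}

#' @export
print.cyl <- function(x, ...) {
  cat(sprintf("%.2f D @ %g°\n", x$magnitude, x$axis))
  invisible(x)
}

#' @export
format.cyl <- function(x, ...) sprintf("%.2f D @ %g°", x$magnitude, x$axis)

is_cyl <- function(x) inherits(x, "cyl")

as_cyl <- function(x, axis = 0) {
  if (is_cyl(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(cyl(x, axis))
  stop_toricity("expected a 'cyl' object or a single magnitude in diopters",
                "toricity_invalid")
}

#' Double-angle coordinates of a cylinder
#'
#' @param v a [cyl()] object.
#' @return Named numeric vector `c(x, y)` with
#'   `x = m*cos(2*theta)`, `y = m*sin(2*theta)` (theta in radians internally).
#' @seealso [da_to_cyl()]
#' @export
cyl_to_da <- function(v) {
  stopifnot(is_cyl(v))
  th <- 2 * v$axis * pi / 180
  c(x = v$magnitude * cos(th), y = v$magnitude * sin(th))
}

#' @rdname cyl_to_da
#' @param x,y double-angle coordinates.
#' @export
da_to_cyl <- function(x, y) {
  m <- sqrt(x^2 + y^2)
  if (m < 1e-12) return(cyl(0, 0))
  cyl(m, norm_axis(atan2(y, x) * 180 / pi / 2))
}

#' Corneal astigmatism from keratometry
#'
#' The corneal cylinder is the difference between the steep and flat
#' principal-meridian powers, oriented along the steep axis.
#'
#' @param k_steep,k_flat steep and flat keratometry in diopters;
#'   `k_steep >= k_flat > 0` is required (the caller passes ordered values).
#' @param steep_axis axis of the steep meridian in degrees.
#' @return A [cyl()] of magnitude `k_steep - k_flat` at `steep_axis`.
#' @examples
#' corneal_cylinder(41, 37, 90)  # 4.00 D @ 90
#' @export
corneal_cylinder <- function(k_steep, k_flat, steep_axis) {
  if (!(k_flat > 0))
    stop_toricity("keratometry must be positive", "toricity_invalid")
  if (k_steep < k_flat)
    stop_toricity("k_steep < k_flat: pass ordered keratometry values",
                  "toricity_invalid")
  cyl(k_steep - k_flat, steep_axis)
}

#' Add two cylinders in the double-angle representation
#'
#' @param a,b [cyl()] objects.
#' @return Their double-angle vector sum as a [cyl()].
#' @export
add_cylinders <- function(a, b) {
  da <- cyl_to_da(a) + cyl_to_da(b)
  da_to_cyl(da[["x"]], da[["y"]])
}

#' @export
`+.cyl` <- function(e1, e2) add_cylinders(e1, e2)

#' Cross cylinder of corneal astigmatism and surgically induced astigmatism
#'
#' The total astigmatism a toric IOL must correct is the vector sum of the
#' measured corneal cylinder and the surgically induced astigmatism (SIA)
#' from the incision. With zero SIA the cross cylinder equals the corneal
#' cylinder exactly.
#'
#' @param corneal corneal cylinder, a [cyl()].
#' @param sia surgically induced astigmatism, a [cyl()] (or 0).
#' @return The combined cylinder as a [cyl()].
#' @examples
#' cross_cylinder(cyl(4, 90), cyl(0, 0))   # unchanged
#' cross_cylinder(cyl(3, 90), cyl(3, 0))   # full cancellation
#' @export
cross_cylinder <- function(corneal, sia) {
  sia <- as_cyl(sia)
  if (sia$magnitude == 0) return(corneal)  # exact, not just to tolerance
  add_cylinders(corneal, sia)
}

# a cylinder's additive inverse: same magnitude, axis rotated 90 degrees
negate_cylinder <- function(v) cyl(v$magnitude, v$axis + 90)
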