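#' @name srkt
#' @title SRK/T sphere power formula
#'
#' @description
#' The SRK/T theoretical formula predicts the postoperative spherical
#' equivalent from axial length, mean keratometry, IOL sphere power and a
#' lens-family A-constant. The chain is the published 1990 form:
#' corneal radius `r = 337.5/K`; a corrected axial length for long eyes;
#' corneal width and height; an estimated lens position (ELP) as corneal
#' height plus an offset derived from the A-constant; a retinal-thickness
#' correction to the optical axial length; and a thin-lens vergence solved at
#' the spectacle plane (12 mm vertex). The square-root operand in the corneal
#' height is clamped at zero for extreme flat-radius/wide-cornea
#' combinations, with a warning, per the standard guard.
#'
#' Refractive indices: retina-side aqueous/vitreous `na = 1.336`, keratometric
#' index difference `nc - 1 = 0.333`.
NULL

# The geometry of the eye model depends on (AL, K, A) only -- not on the IOL
# power -- so inversion computes it once.
srkt_geometry <- function(al, k, a_constant) {
  r <- 337.5 / k
  lcor <- if (al > 24.2) -3.446 + 1.715 * al - 0.0237 * al^2 else al
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k
  h2 <- r^2 - cw^2 / 4
  clamped <- h2 < 0
  if (clamped) {
    warning("SRK/T corneal-height operand negative; clamped to 0 (extreme K/AL)",
            call. = FALSE)
    h2 <- 0
  }
  h <- r - sqrt(h2)
  acd_const <- 0.62467 * a_constant - 68.747
  elp <- h + (acd_const - 3.336)
  lopt <- al + 0.65696 - 0.02029 * al  # retinal thickness correction
  list(r = r, elp = elp, lopt = lopt, clamped = clamped)
}

# vergence solved for spectacle-plane refraction at a given IOL power
srkt_refraction_at <- function(geom, power, vertex = 12) {
  na <- 1.336
  ncm1 <- 0.333
  with(geom, {
    q <- (lopt - elp) * (na * r - ncm1 * elp)
    num <- 1000 * na * (na * r - ncm1 * lopt) - power * q
    den <- na * (vertex * (na * r - ncm1 * lopt) + lopt * r) - 0.001 * power * q
    num / den
  })
}

#' Predicted refraction for a given IOL sphere power
#'
#' @param case a [biometry_case()]; only axial length and mean K enter.
#' @param iol_sphere IOL sphere power in diopters, within \[-10, 40\].
#' @param constants an [iol_constants()].
#' @return Predicted postoperative spherical equivalent (diopters, spectacle
#'   plane).
#' @examples
#' b <- biometry_case(24, 43, 43)
#' srkt_predicted_refraction(b, 21, iol_constants(118.4))
#' @export
srkt_predicted_refraction <- function(case, iol_sphere, constants) {
  stopifnot(inherits(case, "biometry_case"), inherits(constants, "iol_constants"))
  if (iol_sphere < -10 || iol_sphere > 40)
    stop_toricity("iol_sphere outside [-10, 40] D", "toricity_invalid")
  geom <- srkt_geometry(case$axial_length, mean_k(case), constants$a_constant)
  srkt_refraction_at(geom, iol_sphere)
}

#' Invert SRK/T for the target refraction
#'
#' Finds the IOL sphere power whose predicted refraction equals the case's
#' target (plano by default), by bracketed root-finding on the continuous
#' power over \[-10, 40\] D, then rounds to the commercial step.
#'
#' @inheritParams srkt_predicted_refraction
#' @return The rounded power in diopters, with the continuous root attached
#'   as attribute `"continuous"`.
#' @examples
#' invert_for_target(biometry_case(21, 37, 41), iol_constants(118.8))  # 34
#' @export
invert_for_target <- function(case, constants) {
  stopifnot(inherits(case, "biometry_case"), inherits(constants, "iol_constants"))
  geom <- srkt_geometry(case$axial_length, mean_k(case), constants$a_constant)
  f <- function(p) srkt_refraction_at(geom, p) - case$target_refraction
  lo <- f(-10); hi <- f(40)
  if (sign(lo) == sign(hi))
    stop_toricity(
      "no IOL power in [-10, 40] D reaches the target: out-of-range biometry",
      "toricity_no_bracket")
  root <- stats::uniroot(f, c(-10, 40), tol = 1e-6)$root
  structure(round_to_step(root, constants$rounding_step), continuous = root)
}

#' SRK/T estimated lens position
#'
#' The ELP (distance from cornea to the implanted lens, mm) implied by the
#' SRK/T geometry; increases with axial length and with mean K. Used by the
#' vergence toricity model to make the ratio biometry-dependent.
#'
#' @param axial_length axial length in mm.
#' @param k mean keratometry in diopters.
#' @param a_constant lens-family A-constant.
#' @return ELP in mm.
#' @export
srkt_elp <- function(axial_length, k, a_constant) {
  srkt_geometry(axial_length, k, a_constant)$elp
}
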