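#' A toric IOL model
#'
#' @param name lens identifier (e.g. `"SN6AT8"`).
#' @param cylinder_iol_plane cylinder power at the IOL plane, diopters (> 0):
#'   the difference between the lens's steep- and flat-meridian powers.
#' @param sphere_min,sphere_max available sphere power range, diopters.
#' @param a_constant SRK/T A-constant used to pick the sphere power.
#' @return A one-row `lens_catalog` data frame.
#' @export
lens_model <- function(name, cylinder_iol_plane, sphere_min = 0,
                       sphere_max = 40, a_constant = 118.8) {
  lens_catalog(data.frame(name = as.character(name),
                          cylinder_iol_plane_D = cylinder_iol_plane,
                          sphere_min_D = sphere_min, sphere_max_D = sphere_max,
                          a_constant = a_constant,
                          stringsAsFactors = FALSE))
}

#' A catalog of toric lenses
#'
#' @param df data.frame with columns `name`, `cylinder_iol_plane_D`,
#'   `sphere_min_D`, `sphere_max_D`, `a_constant`. Duplicate names are
#'   rejected; cylinder powers must be positive and sphere ranges ordered.
#' @return The validated data frame with class `lens_catalog` prepended.
#' @seealso [read_catalog()], [default_catalog()]
#' @export
lens_catalog <- function(df) {
  need <- c("name", "cylinder_iol_plane_D", "sphere_min_D", "sphere_max_D",
            "a_constant")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_toricity(paste("catalog lacks columns:",
                        paste(missing_cols, collapse = ", ")),
                  "toricity_invalid")
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$name))
    stop_toricity("duplicate lens names in catalog", "toricity_invalid")
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$cylinder_iol_plane_D[i]) || df$cylinder_iol_plane_D[i] <= 0)
      stop_toricity(sprintf("catalog row %d: field cylinder_iol_plane_D must be > 0", i),
                    "toricity_invalid")
    if (df$sphere_min_D[i] > df$sphere_max_D[i])
      stop_toricity(sprintf("catalog row %d: field sphere_min_D exceeds sphere_max_D", i),
                    "toricity_invalid")
    if (df$a_constant[i] < 110 || df$a_constant[i] > 125)
      stop_toricity(sprintf("catalog row %d: field a_constant outside [110, 125]", i),
                    "toricity_invalid")
  }
  class(df) <- c("lens_catalog", "data.frame")
  df
}

#' Toricity models for the calculator simulator
#'
#' Three families of rule a calculator might use to turn IOL-plane cylinder
#' into corneal-plane effect:
#' \describe{
#'   \item{constant}{one fixed ratio for every eye (the behaviour of several
#'     first-generation commercial calculators, typically near 1.46).}
#'   \item{table}{a tabulated surface over (axial length, mean K), evaluated
#'     by bilinear interpolation and clamped at the grid edges.}
#'   \item{vergence}{physically derived: for each corneal meridian of power
#'     \eqn{K_m}, the thin-lens IOL power at separation ELP is
#'     \eqn{P_m = n/(AL - ELP) - n/(n/K_m - ELP)} with \eqn{n = 1.336}
#'     (distances in meters), and
#'     \eqn{\tau = (P_{flat} - P_{steep}) / (K_{steep} - K_{flat})}.
#'     The ELP is a fixed `elp_mm`, or, when `elp_mm` is `NULL`, derived from
#'     the case's biometry through the SRK/T geometry ([srkt_elp()]), which
#'     makes the ratio increase with axial length and mean K.}
#' }
#'
#' @param kind `"constant"`, `"table"` or `"vergence"`.
#' @param constant_value the fixed ratio (kind `"constant"`); must lie in
#'   (1, 3), the physiological range.
#' @param axial_lengths,mean_ks,values table nodes (kind `"table"`):
#'   increasing axis vectors and a `length(mean_ks)` x `length(axial_lengths)`
#'   matrix of ratios (rows = mean K ascending), all in (1, 3).
#' @param elp_mm fixed effective lens position in mm (kind `"vergence"`), or
#'   `NULL` to derive the ELP per case from SRK/T.
#' @param a_constant A-constant for the SRK/T-derived ELP (kind `"vergence"`,
#'   used only when `elp_mm` is `NULL`).
#' @return An object of class `toricity_model`.
#' @examples
#' toricity_model("constant", constant_value = 1.46)
#' toricity_model("vergence", elp_mm = 5)
#' @export
toricity_model <- function(kind = c("constant", "table", "vergence"),
                           constant_value = NULL, axial_lengths = NULL,
                           mean_ks = NULL, values = NULL, elp_mm = NULL,
                           a_constant = 118.8) {
  kind <- match.arg(kind)
  m <- structure(list(kind = kind), class = "toricity_model")
  check_range <- function(v, what) {
    if (any(!is.finite(v)) || any(v <= 1) || any(v >= 3))
      stop_toricity(paste(what, "must lie in (1, 3)"), "toricity_invalid")
  }
  if (kind == "constant") {
    if (is.null(constant_value))
      stop_toricity("constant model needs constant_value", "toricity_invalid")
    check_range(constant_value, "constant toricity ratio")
    m$constant_value <- constant_value
  } else if (kind == "table") {
    if (is.null(values) || length(values) == 0)
      stop_toricity("table model with empty table", "toricity_invalid")
    values <- as.matrix(values)
    if (is.null(axial_lengths) || is.null(mean_ks) ||
        nrow(values) != length(mean_ks) || ncol(values) != length(axial_lengths))
      stop_toricity("table dimensions must match mean_ks x axial_lengths",
                    "toricity_invalid")
    if (is.unsorted(axial_lengths, strictly = TRUE) ||
        is.unsorted(mean_ks, strictly = TRUE))
      stop_toricity("table axes must be strictly increasing", "toricity_invalid")
    check_range(values, "tabulated toricity ratios")
    m$axial_lengths <- axial_lengths
    m$mean_ks <- mean_ks
    m$values <- values
  } else {
    m$elp_mm <- elp_mm
    m$a_constant <- a_constant
  }
  m
}

# bilinear interpolation on a rectilinear grid, clamped at the edges
bilinear <- function(xs, ys, z, x, y) {
  x <- min(max(x, xs[1]), xs[length(xs)])
  y <- min(max(y, ys[1]), ys[length(ys)])
  i <- max(findInterval(x, xs, rightmost.closed = TRUE), 1L)
  j <- max(findInterval(y, ys, rightmost.closed = TRUE), 1L)
  i2 <- min(i + 1L, length(xs)); j2 <- min(j + 1L, length(ys))
  tx <- if (i2 == i) 0 else (x - xs[i]) / (xs[i2] - xs[i])
  ty <- if (j2 == j) 0 else (y - ys[j]) / (ys[j2] - ys[j])
  unname((1 - tx) * (1 - ty) * z[j, i] + tx * (1 - ty) * z[j, i2] +
    (1 - tx) * ty * z[j2, i] + tx * ty * z[j2, i2])
}

#' Evaluate a toricity model for one eye
#'
#' @param model a [toricity_model()].
#' @param case a [biometry_case()].
#' @param elp optional ELP override in mm (vergence kind only).
#' @return The toricity ratio (dimensionless) the model assigns to this eye.
#'   A vergence ratio outside (1, 3) triggers a warning.
#' @export
tau_for_case <- function(model, case, elp = NULL) {
  stopifnot(inherits(model, "toricity_model"), inherits(case, "biometry_case"))
  tau <- switch(model$kind,
    constant = model$constant_value,
    table = bilinear(model$axial_lengths, model$mean_ks, model$values,
                     case$axial_length, mean_k(case)),
    vergence = {
      e_mm <- elp %||% model$elp_mm %||%
        srkt_elp(case$axial_length, mean_k(case), model$a_constant)
      tau_vergence(case$axial_length, case$k_flat, case$k_steep, e_mm)
    })
  if (model$kind == "vergence" && (tau <= 1 || tau >= 3))
    warning(sprintf("vergence toricity ratio %.3f outside the physiological range (1, 3)", tau),
            call. = FALSE)
  tau
}

# meridional thin-lens vergence; distances in meters, n = 1.336
tau_vergence <- function(al_mm, k_flat, k_steep, elp_mm) {
  n <- 1.336
  al <- al_mm / 1000
  e <- elp_mm / 1000
  p_meridian <- function(k) n / (al - e) - n / (n / k - e)
  if (k_steep - k_flat < 1e-9) {   # degenerate: take the derivative limit
    h <- 5e-3
    return((p_meridian(k_flat - h) - p_meridian(k_flat + h)) / (2 * h))
  }
  (p_meridian(k_flat) - p_meridian(k_steep)) / (k_steep - k_flat)
}

#' Simulate a toric IOL calculator
#'
#' The forward stand-in for a commercial web calculator: combines the
#' corneal cylinder with the SIA into the cross cylinder, assigns a toricity
#' ratio from `model`, computes each catalog lens's residual
#' `r = C_c - L_c/tau`, and prints what a web calculator prints -- lens name,
#' residual magnitude (rounded to `digits` decimals) and residual axis (the
#' cross-cylinder axis, flipped 90 degrees when over-correcting). Only
#' lenses whose sphere range covers the SRK/T-inverted sphere power are
#' recommended.
#'
#' @param case a [biometry_case()].
#' @param catalog a [lens_catalog()].
#' @param model a [toricity_model()].
#' @param digits decimals of the printed residual (default 2, what real
#'   calculators display; `Inf` disables rounding).
#' @param policy `"min_abs"` ranks lenses by |residual| ascending (ties to
#'   the lower cylinder, the conventional preference for under-correction);
#'   `"no_overcorrection"` additionally prefers every under-correcting lens
#'   over any over-correcting one, the behaviour of calculators that avoid
#'   axis flip.
#' @param elp optional ELP override passed to [tau_for_case()].
#' @return An object of class `calculator_result`: `recommendations` (data
#'   frame sorted by the policy, printed fields plus `residual_exact_D`),
#'   `selected` (first row's lens name), `tau`, `sphere_D`, `cross_cylinder`.
#'   An empty recommendation list (with a warning) when no lens covers the
#'   required sphere power.
#' @examples
#' res <- simulate_calculator(biometry_case(21, 37, 41),
#'                            default_catalog("alcon_acrysof"),
#'                            toricity_model("constant", constant_value = 1.46))
#' res$recommendations
#' @export
simulate_calculator <- function(case, catalog, model, digits = 2,
                                policy = c("min_abs", "no_overcorrection"),
                                elp = NULL) {
  stopifnot(inherits(catalog, "lens_catalog"))
  policy <- match.arg(policy)
  if (nrow(catalog) == 0)
    stop_toricity("empty lens catalog", "toricity_invalid")
  cc <- cross_cylinder(
    corneal_cylinder(case$k_steep, case$k_flat, case$steep_axis), case$sia)
  tau <- tau_for_case(model, case, elp = elp)

  # required sphere per A-constant (catalogs usually share one)
  sphere_for_a <- vapply(unique(catalog$a_constant), function(a) {
    as.numeric(invert_for_target(case, iol_constants(a)))
  }, numeric(1))
  names(sphere_for_a) <- as.character(unique(catalog$a_constant))
  sphere <- sphere_for_a[as.character(catalog$a_constant)]
  ok <- sphere >= catalog$sphere_min_D & sphere <= catalog$sphere_max_D

  rec <- catalog[ok, , drop = FALSE]
  if (nrow(rec) == 0) {
    warning("no lens sphere range covers the required power; empty recommendation",
            call. = FALSE)
    empty <- data.frame(name = character(), cylinder_iol_plane_D = numeric(),
                        sphere_D = numeric(), residual_D = numeric(),
                        residual_axis_deg = numeric(),
                        residual_exact_D = numeric())
    return(structure(list(recommendations = empty, selected = NA_character_,
                          tau = tau, cross_cylinder = cc, case = case),
                     class = "calculator_result"))
  }
  r_exact <- cc$magnitude - rec$cylinder_iol_plane_D / tau
  axis <- ifelse(r_exact >= 0, cc$axis, norm_axis(cc$axis + 90))
  out <- data.frame(name = rec$name,
                    cylinder_iol_plane_D = rec$cylinder_iol_plane_D,
                    sphere_D = as.numeric(sphere[ok]),
                    residual_D = round_half_up(abs(r_exact), digits),
                    residual_axis_deg = axis,
                    residual_exact_D = r_exact,
                    stringsAsFactors = FALSE)
  ord <- if (policy == "no_overcorrection") {
    order(r_exact < 0, abs(r_exact), out$cylinder_iol_plane_D)
  } else {
    order(abs(r_exact), out$cylinder_iol_plane_D)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(recommendations = out, selected = out$name[1], tau = tau,
                 cross_cylinder = cc, case = case),
            class = "calculator_result")
}

#' @export
print.calculator_result <- function(x, ...) {
  cat(sprintf("cross cylinder %s | recommended:\n", format(x$cross_cylinder)))
  if (nrow(x$recommendations) == 0) {
    cat("  (none)\n")
  } else {
    r <- x$recommendations
    for (i in seq_len(nrow(r)))
      cat(sprintf("  %-10s sphere %5.1f D  residual %.2f D @ %g°%s\n",
                  r$name[i], r$sphere_D[i], r$residual_D[i],
                  r$residual_axis_deg[i], if (i == 1) "  <- selected" else ""))
  }
  invisible(x)
}

#' A calculator interface for probing
#'
#' Wraps a catalog + toricity model into the black-box function signature
#' [probe()] consumes: `function(case)` returning the printable
#' recommendation table (`name`, `cylinder_iol_plane_D`, `residual_D`,
#' `residual_axis_deg`). With `digits = 2` (default) the probe sees exactly
#' what a human transcribing a web calculator would see.
#'
#' @inheritParams simulate_calculator
#' @return A function of a [biometry_case()].
#' @export
simulated_calculator <- function(catalog, model, digits = 2,
                                 policy = "min_abs") {
  force(catalog); force(model); force(digits); force(policy)
  function(case) {
    res <- simulate_calculator(case, catalog, model, digits = digits,
                               policy = policy)
    res$recommendations[, c("name", "cylinder_iol_plane_D", "residual_D",
                            "residual_axis_deg")]
  }
}
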