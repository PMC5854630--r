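#' Round half away from zero
#'
#' Commercial IOL calculators print diopter values rounded half-up (0.005 ->
#' 0.01), unlike [base::round()]'s round-half-to-even. Used for every printed
#' diopter/ratio in the package; internal values are never truncated.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (use `Inf` for no rounding).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  if (!is.finite(digits) && digits > 0) return(x)
  f <- 10^digits
  # tiny nudge guards against 0.005 stored as 0.00499999999...
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# snap a continuous power to the commercial step grid (0.5 D by default)
round_to_step <- function(x, step) round_half_up(x / step, 0) * step

# normalize a cylinder axis into [0, 180)
norm_axis <- function(axis) ((axis %% 180) + 180) %% 180

# unsigned distance between two axes on the 180-degree circle, in [0, 90]
axis_distance <- function(a, b) {
  d <- abs(norm_axis(a) - norm_axis(b))
  pmin(d, 180 - d)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_toricity <- function(msg, class) {
  stop(structure(class = c(class, "toricity_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
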