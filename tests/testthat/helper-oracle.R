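# Independent straight-line transcription of the published SRK/T chain,
# written before (and kept independent of) the package implementation. It is
# the oracle the production code is checked against: every constant is typed
# out inline and the whole computation is one expression sequence with no
# shared helpers.
oracle_srkt_refraction <- function(al, k, power, a_constant, vertex = 12) {
  r <- 337.5 / k
  lcor <- if (al <= 24.2) al else -3.446 + 1.715 * al - 0.0237 * al * al
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k
  operand <- r * r - (cw * cw) / 4
  if (operand < 0) operand <- 0
  h <- r - sqrt(operand)
  acd_const <- 0.62467 * a_constant - 68.747
  acd_est <- h + acd_const - 3.336
  rethick <- 0.65696 - 0.02029 * al
  lopt <- al + rethick
  na <- 1.336
  ncm1 <- 0.333
  n1 <- na * r - ncm1 * lopt
  n2 <- na * r - ncm1 * acd_est
  (1000 * na * n1 - power * (lopt - acd_est) * n2) /
    (na * (vertex * n1 + lopt * r) - 0.001 * power * (lopt - acd_est) * n2)
}

# oracle inversion by bisection (independent of stats::uniroot)
oracle_plano_power <- function(al, k, a_constant, target = 0) {
  lo <- -10; hi <- 40
  flo <- oracle_srkt_refraction(al, k, lo, a_constant) - target
  fhi <- oracle_srkt_refraction(al, k, hi, a_constant) - target
  stopifnot(sign(flo) != sign(fhi))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    fm <- oracle_srkt_refraction(al, k, mid, a_constant) - target
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# a compact in-code catalog used where the shipped CSVs are not themselves
# under test
test_catalog <- function(cyls = c(1.50, 2.25, 3.00, 3.75, 4.50, 5.25, 6.00),
                         a_constant = 118.8) {
  lens_catalog(data.frame(
    name = sprintf("T%02d", seq_along(cyls)),
    cylinder_iol_plane_D = cyls,
    sphere_min_D = 0, sphere_max_D = 40, a_constant = a_constant))
}
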