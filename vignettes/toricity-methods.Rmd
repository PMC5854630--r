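---
title: "Extracting and probing toricity ratios of toric IOL calculators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and probing toricity ratios of toric IOL calculators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(toricity)
```

## The model

A toric IOL's cylinder is specified at the IOL plane (`L_c`, diopters), but
the astigmatism it must correct lives at the corneal plane. The toricity
ratio `τ` is the factor between the two: a lens of cylinder `L_c` corrects
`L_c/τ` at the cornea, and `τ > 1` because the lens sits behind the cornea
by the effective lens position (ELP). A calculator that corrects the cross
cylinder `C_c` therefore predicts a residual

```
r = C_c − L_c/τ
```

with the sign convention that under-correction (`r > 0`) leaves the
residual at the corrected axis while over-correction (`r < 0`) flips the
printed axis by 90°. Inverting,

```
τ = L_c / (C_c − r),
```

every quantity on the right is either an input to, or printed output of,
any toric calculator — so `τ` can be extracted per run with no knowledge of
the calculator's internals. `extract_toricity()` implements this;
`signed_residual()` implements the axis-to-sign convention with a ±5°
matching window (real calculators print exact 0°/90° flips; the window
tolerates formatted output). A residual axis oblique to both windows would
indicate toric-axis misalignment modelling, which scalar extraction cannot
represent; it is an error by design, not silently signed.

With zero surgically induced astigmatism (SIA) the cross cylinder equals
the keratometric cylinder `K_steep − K_flat` exactly, and the extraction
needs no vector arithmetic. With non-zero SIA, `cross_cylinder()` combines
the two in the double-angle representation — `(m, θ) → (m cos 2θ,
m sin 2θ)` — where cylinders add componentwise; the residual sign is then
judged against the *combined* axis.

## Generating the sphere input: SRK/T

Probing a calculator requires a plausible sphere power per test eye. We use
the published SRK/T chain (keratometric radius `337.5/K`, long-eye axial
correction, corneal width/height with the square-root operand clamped at
zero, A-constant-derived ELP offset, retinal thickness correction, thin-lens
vergence at a 12 mm vertex) and invert it for a plano target by bracketed
root-finding over [−10, 40] D (tolerance 1e−6 D), then round to the 0.5 D
commercial step. The required power depends on keratometry only through its
mean, which the tests assert by permuting flat/steep splits at fixed mean.

No A-constant is published for the probed calculators. We calibrate: the
worked example requires that a 21.00 mm eye with mean K 39.0 D invert to a
34.0 D sphere, which pins A ≈ 118.82; the shipped catalogs use **A =
118.8** (continuous power 33.96 D, rounding to 34.0). The same biometry is
stated to need a 30.0 D lens on the Bausch & Lomb calculator — a gap far
larger than typical constant differences, and no constant is given — so the
enVista catalog ships A = 116.5 (which reproduces 30.0 D) as an explicitly
synthetic, editable calibration rather than a claim about the real lens.
Formula choice is not load-bearing for extraction: the sphere power only
has to be *a* consistent input.

## The calculator simulator

`simulate_calculator()` is the stand-in for the commercial web calculators
(which are out of scope to access): it computes `C_c`, assigns `τ` from a
`toricity_model()`, applies the forward model per catalog lens, and prints
exactly the fields a web calculator shows — lens name, residual magnitude
rounded to 2 decimals, residual axis. The extractor consumes only these
printable fields, keeping the black-box contract honest; the unrounded
residual is retained separately so the simulator–extractor closure
(recovery of `τ` to 1e−9) can be tested upstream of display rounding.

Three model families:

* **constant** — one ratio for all eyes, the behaviour of several
  first-generation calculators (typically near 1.46). Valid range (1, 3).
* **table** — a tabulated `τ(AL, mean K)` surface, bilinearly interpolated
  and clamped at the edges; emulates variable-ratio calculators whose rule
  is unknown.
* **vergence** — physically derived: per corneal meridian `K_m`, the
  thin-lens IOL power at separation ELP is
  `P_m = n/(AL − ELP) − n/(n/K_m − ELP)` with `n = 1.336` (meters), and
  `τ = (P_flat − P_steep)/(K_steep − K_flat)`. As ELP → 0 the ratio tends
  to 1; it increases with ELP and with mean K. With a *fixed* ELP the
  axial-length term cancels in the meridional difference, so to make `τ`
  biometry-dependent the default derives ELP per case from the SRK/T
  geometry (`elp_mm = NULL`), which grows with both AL and mean K and
  reproduces the qualitative trend observed in variable-ratio calculators.
  This is a hypothesis-shaped emulation, not a reconstruction of any
  manufacturer's rule.

Lens selection was a genuinely open design point: ranking by smallest
|residual| is the documented contract, but the calculator in the original
Alcon worked example recommended the 5.25 D lens (+0.40 D) when a 6.00 D
lens would have left only −0.11 D — i.e. it avoided over-correction. Both
behaviours are provided (`policy = "min_abs"` default,
`"no_overcorrection"`); the extracted ratio is unaffected because under a
single-`τ` model every lens of the same run yields the same `τ`. Ties at
equal |residual| go to the lower cylinder (the conventional clinical
preference for under-correction).

## The probing protocol

`probe_grid()` crosses axial lengths {21, 24, 27} mm with mean K
{39, 43, 47} D — short/average/long eyes by flat/average/steep corneas —
with a 4.00 D test cylinder split ±2.00 D about the mean at a 90° steep
axis and zero SIA. The defaults are the published protocol's values; the
cylinder is configurable because larger cylinders resolve `τ` with less
display-rounding error, and the extracted ratio is invariant to both the
steep axis and the flat/steep split (asserted by tests). Per cell, the
recommended lens with the smallest printed residual is extracted; a cell
where extraction is impossible (oblique axis, residual ≥ attempted
correction) is recorded invalid with its reason and the matrix is still
returned. The matrix is printed with mean K descending down rows and axial
length ascending across columns, matching the published table orientation.

**Classification.** A calculator is called constant-ratio when
max − min of the valid cells ≤ 0.02 — one unit in the second printed
decimal on each side, enough to absorb a lone display-rounding artifact
(e.g. a single 1.42 cell among 1.43s) while any genuine variable trend
(spreads ≥ 0.1 across the grid) is far outside it. Fewer than two valid
cells is "indeterminate". The constant's reported value is the cell median.

## What the synthetic data does and does not establish

The simulator generates all probe inputs; no manufacturer calculator is
accessed. A green probe test therefore establishes the *closure* property —
whatever ratio rule the simulator is configured with, the protocol recovers
it (constants to within 0.005 through the 2-decimal display; table nodes
exactly when display rounding is disabled) — and that the published
worked-example arithmetic reproduces. It does **not** establish the cell
values of any real calculator's matrix beyond those printed examples: real
variable-ratio matrices encode live proprietary internals that a desk-scale
emulation cannot recover. The hand-transcript mode
(`transcript_calculator()`) exists precisely so a user can run the nine
cells against a real calculator and feed the printed outputs back in.

## Numerical choices

* Axes in degrees on [0, 180); double angles in radians internally; a
  zero-magnitude cylinder reports axis 0 by convention.
* Printed diopters and displayed ratios round half *away from zero* (what
  calculators print), not banker's rounding; internal values are never
  truncated.
* Root-finding: `stats::uniroot`, tolerance 1e−6 D, bracket [−10, 40] D;
  no bracket is an error naming out-of-range biometry.
* The SRK/T corneal-height square root clamps a negative operand to zero
  with a warning (extreme flat-radius/wide-cornea corners of the test
  lattice), mirroring the standard guard; the independent test oracle
  clamps identically.
* Ratio sanity range (1, 3) enforced at model construction (constant,
  table) and warned about for vergence outputs.

## Known limitations

* Extraction assumes the residual axis is parallel or perpendicular to the
  corrected axis; toric-axis misalignment (oblique residuals) requires
  vector extraction and is out of scope.
* One `τ` per calculator run: per-lens display rounding in real calculators
  can make co-recommended lenses imply ratios differing in the last printed
  digit (1.32 vs 1.33), which this package treats as display noise, not a
  per-cylinder ratio.
* The vergence model is thin-lens; thick-lens or ray-traced pseudophakic
  optics, posterior corneal astigmatism, and post-refractive-surgery K
  adjustment are not modelled.
* No confidence intervals on extracted ratios: the inputs are printed
  numbers, not noisy measurements.
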