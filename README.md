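# toricity

Tools for extracting the **toricity ratio** used by any toric intraocular
lens (tIOL) calculator, and for probing whether a calculator uses a
*constant* or a *variable* ratio.

## The problem

A toric IOL corrects corneal astigmatism, but the lens sits a few
millimeters behind the cornea, so its cylinder power at the IOL plane
(`L_c`, published by the manufacturer) is *not* the astigmatism it corrects
at the corneal plane. The conversion factor is the toricity ratio

```
τ = L_c / (corneal-plane toricity),     τ > 1
```

Commercial calculators do not disclose the τ they use, yet the choice
matters: a fixed "average" τ mis-corrects short/long eyes and flat/steep
corneas. The ratio is nevertheless recoverable from what any calculator
already prints. If a calculator attempts to correct a cross cylinder `C_c`
(corneal cylinder combined vectorially with the surgically induced
astigmatism) with a lens of cylinder `L_c` and predicts residual
astigmatism `r`, then

```
r = C_c − L_c/τ        (forward model)
τ = L_c / (C_c − r)    (extraction)
```

where `r` is signed: positive (under-correction) when the residual axis is
unchanged, negative (over-correction) when the axis flips 90°. The package
implements this extraction, the double-angle cylinder arithmetic behind
`C_c`, the SRK/T sphere-power formula and its inversion to a plano target
(to generate the sphere input a calculator expects), a forward simulator of
toric calculators (constant, tabulated, and vergence/ELP-derived τ models),
and the probing protocol: a 3 × 3 grid of short/average/long axial lengths
(21, 24, 27 mm) × low/average/high mean keratometry (39, 43, 47 D), one
extraction per cell, classified constant vs variable.

Intended users: cataract/refractive surgeons and IOL-calculation
researchers auditing black-box calculators.

## Worked example

One published calculator run: flat K 37.0 D, steep K 41.0 D at 90° (mean
K 39.0 D, corneal cylinder 4.00 D), SIA 0, axial length 21.00 mm. Inverting
SRK/T gives the 34.0 D sphere; the calculator recommended a 5.25 D-cylinder
lens with residual +0.40 D at the unchanged axis:

```r
library(toricity)
invert_for_target(biometry_case(21, 37, 41), iol_constants(118.8))
#> [1] 34
extract_toricity(5.25, cyl(4.00, 90), 0.40, residual_axis = 90)
#> toricity ratio 1.46  (lens 5.25 D at IOL plane / 3.60 D at corneal plane; residual +0.40 D)
```

The lens corrects 4.00 − 0.40 = 3.60 D at the corneal plane, so
τ = 5.25/3.60 = 1.46 — the constant used by several first-generation
calculators.

Probing a simulated calculator whose τ follows thin-lens vergence at the
SRK/T-estimated lens position (a *variable*-ratio calculator):

```r
calc <- simulated_calculator(default_catalog("abbott_tecnis"),
                             toricity_model("vergence", elp_mm = NULL,
                                            a_constant = 118.8))
probe(calc)
#> Toricity ratio matrix (rows: mean K [D] desc; cols: AL [mm] asc)
#>      21   24   27
#> 47 1.47 1.68 1.95
#> 43 1.36 1.47 1.56
#> 39 1.28 1.35 1.40
#> classification: variable (tolerance 0.02)
```

τ increases with axial length and mean K — the qualitative signature of a
calculator that accounts for effective lens position. A constant-τ
simulator instead yields nine identical cells and
`classification: constant`.

To probe a *real* web calculator, run the nine grid cells by hand
(`build_cases(probe_grid(), iol_constants(118.8))` lists the inputs to
type), transcribe each recommendation into a CSV, and use
`probe(transcript_calculator("cells.csv"))`.

## Command line

```sh
exec/toricity extract --lens-cyl 5.25 --kc 4.00 --residual 0.40 --residual-axis 90 --steep-axis 90
exec/toricity power --al 21 --kflat 37 --ksteep 41 --target 0 --aconst 118.8
exec/toricity probe --model constant:1.46 --csv matrix.csv
exec/toricity fixtures --dir examples/
```

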