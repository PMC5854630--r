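Package: toricity
Title: Toricity Ratios of Toric Intraocular Lens Calculators
Version: 0.1.0
Authors@R: person("The", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Extracts the toricity ratio -- the factor converting a toric
    intraocular lens's cylinder power at the IOL plane into its
    astigmatism-correcting effect at the corneal plane -- from the inputs
    and outputs of any toric IOL calculator, treated as a black box.
    Provides double-angle astigmatism vector arithmetic, the SRK/T sphere
    power formula and its inversion to a plano target, a forward simulator
    of toric calculators (constant, tabulated, and vergence-derived
    toricity models), and a grid-probing protocol that assembles a
    3 x 3 axial-length by mean-keratometry matrix of extracted ratios and
    classifies a calculator as using a constant or a variable ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
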