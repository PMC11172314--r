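Package: filabs
Title: Phase Diagrams, Protein Partition and Stability in Ionic-Liquid
    Aqueous Biphasic Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for aqueous biphasic system (ABS)
    protein-purification workflows built on fluorinated and conventional
    ionic liquids. Fits the Merchuck binodal (solubility) curve to
    cloud-point titration data, solves gravimetric tie-lines by the lever
    rule, converts ternary compositions between weight percent and
    molality, computes liquid-liquid extraction efficiencies, fits 1:1
    mass-action binding isotherms to microscale thermophoresis titrations
    to estimate dissociation constants, fits two-state van't Hoff models
    to differential scanning calorimetry thermograms (melting temperature,
    unfolding enthalpy, Gibbs energy), and quantifies relative lysozyme
    activity from turbidity-decay traces. Seeded synthetic-data
    generators emulate every instrument so the full pipeline is testable
    without measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
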