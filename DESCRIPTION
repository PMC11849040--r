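Package: surfkin
Title: Harmonic Thermochemistry and RRKM/Eckart Kinetics for Surface Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for quantum-chemical studies of
    adsorbate reactions on mineral surfaces: zero-point and thermal
    corrections from partial-Hessian harmonic frequencies, composite
    two-level reaction energy profiles, binding-energy bookkeeping,
    canonical transition-state-theory and RRKM rate constants with
    Eckart tunneling corrections, half-lives, and Arrhenius analysis.
    Includes numerical Hessians on model potentials and a synthetic
    stationary-point generator with known ground truth, so the whole
    pipeline is testable without any electronic-structure calculation.
    The worked example is the dimerization of HCN to iminoacetonitrile
    on forsterite (Mg2SiO4) surfaces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
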