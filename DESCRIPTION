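Package: aerodose
Title: Aerosol Size-Distribution Reduction and Respiratory Dosimetry for
    E-Cigarette Aerosols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reduce e-cigarette aerosol sizing measurements to
    lognormal particle-size distributions and to estimate respiratory-tract
    dose. Implements cascade-impactor data reduction by log-probit regression
    (MMAD and geometric standard deviation), Hatch-Choate diameter
    conversions and aerodynamic-density scaling for mobility-sizer data,
    per-puff mass concentration and consumption metrics, a symmetric
    generation-by-generation lung deposition model (impaction,
    sedimentation, diffusion) yielding head, tracheobronchial, pulmonary,
    total and exhaled mass fractions, formulation-comparison statistics
    with Tukey HSD compact letter displays, and a synthetic-data generator
    that emulates impactor and mobility-sizer instruments so the full
    pipeline can be exercised against known truth.
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
    minpack.lm,
    withr
Config/testthat/edition: 3
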