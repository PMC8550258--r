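Package: periprot
Title: Plasma Protein Concentration Trajectories in Pregnant and Postpartum Women
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distributional regression for longitudinal serum albumin and plasma
    alpha-1-acid glycoprotein (AAG) concentrations in pregnant and postpartum
    women. Fits penalized B-spline (P-spline) location curves with selectable
    error families (normal, two-component normal mixture, two-piece skew
    normal) and variance models, selects among candidate models by generalized
    AIC, estimates time-dependent quantile curves and validates them by
    coverage concordance, fits cubic smoothing splines for sparse analytes,
    approximates fitted mean curves by low-degree polynomials, and exports
    mean/quantile/sampling "computational functions" as JSON bundles for
    virtual-population generation in physiologically based pharmacokinetic
    (PBPK) modelling. Includes a seeded synthetic-data generator emulating the
    longitudinal study structure the methods were designed for.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
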