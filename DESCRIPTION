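Package: aucpool
Title: Pooled-Plasma AUC Estimation and Exposure-Based Quality-Marker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, validation and analysis tools for the pooled-plasma AUC
    (Hamilton) method in semi-quantitative pharmacokinetic screening of
    multi-component medicines. Computes per-time-point plasma pooling volumes
    proportional to linear trapezoid weights so that a single pooled
    measurement times the sampling span equals the serial trapezoidal AUC;
    estimates and compares exposures from pooled and serial data; ranks
    compound exposures, computes top-N cumulative fractions and cross-species
    shares; screens quality-marker candidates by Pearson correlation of
    time-percentage profiles against a reference compound; and simulates
    one-compartment oral parent/phase-II-metabolite cohorts with analytical
    noise and LLOQ censoring for end-to-end validation. Includes a minimal
    high-resolution extracted-ion-chromatogram (EIC) quantifier at ppm mass
    tolerance with optional internal-standard normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mzR
Config/testthat/edition: 3
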