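Package: mcpsize
Title: Stereology and Light-Scattering Analysis of Bacterial Microcompartment Sizing
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how imaging and ensemble sizing techniques change the
    apparent diameter of bacterial microcompartments (MCPs). Implements the
    stereological model of apparent diameter under ultra-thin sectioning
    (analytic volume-weighted and uniform-plane expectations, Monte-Carlo
    plane sectioning of spheres and irregular convex polyhedra, and
    detection-limit truncation fitting), a calibrated synthetic-measurement
    generator for five imaging techniques plus dynamic light scattering (DLS)
    correlograms and nanoparticle tracking analysis (NTA) samples, second-order
    cumulant analysis of DLS autocorrelation data (Z-average, polydispersity
    index), intensity/number/volume particle-size-distribution reweighting,
    and the full statistical comparison of techniques (descriptive box-plot
    statistics, percent shifts, one-way ANOVA, two-tailed t tests, variance
    ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
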