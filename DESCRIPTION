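Package: nmrmetab
Title: 1H NMR Metabolomics Pipeline with OPLS-DA Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-backed 1H NMR metabolomics analysis pipeline:
    Lorentzian spectrum simulation with known ground truth, spectral
    preprocessing (TSP referencing, asymmetric least squares baseline
    correction, segment alignment, fixed-width bucketing with water
    exclusion, probabilistic quotient normalization, Pareto scaling),
    PCA and two-class OPLS-DA with cross-validated R2Y/Q2Y, S-plot,
    VIP, SUS-plot and Venn partitioning, Benjamini-Hochberg corrected
    fold-change tables, Pearson correlation networks, and small
    utilities for formulation, dose and infarct-volume arithmetic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
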