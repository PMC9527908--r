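Package: ttmorph
Title: 3D Morphometry of Cardiomyocyte Transverse-Tubule Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transverse-tubule (t-tubule) networks of cardiac
    myocytes from 3D segmented label volumes such as those produced from
    serial block-face scanning electron microscopy stacks. Computes
    per-tubule volume, surface area, contour-based equivalent diameter,
    longest-branch length and length normalized to cell width; classifies
    connected components as sarcolemma-connected t-tubules or orphaned
    fragments; aggregates per-cell densities and volume fractions; and
    compares regions (control, infarct-remote, infarct-border) with linear
    mixed models that respect the cell-within-animal clustering of the
    measurements. Includes a parametric synthetic-myocyte phantom generator
    with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    lme4,
    nortest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
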