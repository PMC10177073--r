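Package: ipdtplan
Title: Light Dosimetry and Treatment Planning for Interstitial Photodynamic Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based planning of light delivery for interstitial
    photodynamic therapy (I-PDT) with cylindrical diffuser fibers. Solves the
    optical diffusion equation on tagged tetrahedral meshes with linear (P1)
    finite elements (Dirichlet diffuser sources, Robin outer boundary, steady
    and implicit-Euler transient modes), computes irradiance and rate-based
    light-dose volume histograms, and optimizes per-fiber power and treatment
    time under critical-structure safety limits with the domination sub-maps
    method. Includes synthetic phantom and airway-tumor scene generators,
    an analytic infinite-cylinder oracle for verification, and Lin's
    concordance correlation coefficient for validation against dosimetry
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
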