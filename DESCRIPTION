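Package: sonoqc
Title: Ultrasound Image Quality Assessment and Force-Adaptive Scan Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time quality assessment of B-mode ultrasound frames from three
    image features (correlation against a no-contact reference frame, tissue
    compression extent, and residual speckle noise after adaptive Wiener
    filtering), a gated support-vector-machine classifier mapping the features
    to a binary quality verdict, and a simulated admittance-controlled scan
    loop that adapts probe contact force to the verdict. Includes a synthetic
    B-mode phantom generator with force-dependent compression and noise so the
    whole pipeline runs without hardware, plus SSIM/PSNR utilities for
    comparing algorithm-selected frames with human-selected ones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    e1071,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
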