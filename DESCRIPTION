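Package: nettpat
Title: Learned Network Tikhonov (NETT) Regularization for Limited-Data
    Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for solving the masked limited-data photoacoustic
    tomography (PAT) problem with learned Network Tikhonov (NETT)
    regularization.  Builds a Kaiser-Bessel system-matrix forward operator
    on a circular sensor geometry, stabilizes it by truncated singular
    value decomposition, generates synthetic square-ring training phantoms
    and their basic pseudoinverse reconstructions, trains a residual U-Net
    regularizer of the form ||x - Phi(x)||^2 + beta * smoothed-TV, and
    minimizes the resulting Tikhonov functional with a forward-backward
    (proximal gradient) solver.  Includes a reconstruction study harness
    comparing pseudoinverse, post-processing and NETT reconstructions, and
    a toy-problem experiment that measures Bregman-distance convergence
    rates under a source condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
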