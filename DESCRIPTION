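Package: unmixr
Title: Physically Constrained Linear Unmixing of Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Factorizes hyperspectral imaging data (mass spectrometry
    imaging, scanning probe and electron microscopy spectral cubes,
    X-ray diffraction microscopy) into non-negative endmember spectra
    and spatial abundance maps. Implements truncated SVD, PCA, and
    non-negative matrix factorization under Frobenius or generalized
    Kullback-Leibler losses with L1 sparsity, graph-based spatial
    smoothness, and sum-to-one abundance constraints, together with
    rank-selection diagnostics (consensus dispersion, elbow curvature,
    component-similarity saturation), sliding-window FFT feature
    extraction for structural phase mapping, and a synthetic-cube
    generator for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
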