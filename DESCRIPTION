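Package: sladscan
Title: Autonomous Adaptive Sparse Sampling for Scanning Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale toolkit for supervised dynamic sampling
    (SLADS-Net) on 2D scan grids. Provides a simulated scanning-microscope
    instrument (flake-and-bubble dark-field samples and per-pixel
    diffraction stacks), inverse-distance-weighted and biharmonic
    reconstruction from sparse measurements, an expected-reduction-in-
    distortion (ERD) decision model built from local measurement-state
    features, random Fourier feature kernelization and a fully connected
    neural network, a closed acquisition loop with low-discrepancy
    initialization, batch selection and scan-route optimization, static
    baseline sampling masks, and center-of-mass post-analysis of
    diffraction stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RANN,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
RoxygenNote: 7.3.3
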