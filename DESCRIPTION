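Package: psqigeo
Title: Multi-Task Gaussian Process Mapping of Water Quality with a
    Probabilistic Substance Quality Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geo-spatial modelling of multi-parameter water chemistry with
    multi-task Gaussian process regression (spectral mixture spatial kernel,
    low-rank inter-parameter covariance, quadratic spatial trend), warping of
    bounded concentrations into an unbounded Gaussian model space, automatic
    kernel-complexity and rank selection by cross-validated R2, and a
    regulation-driven Probabilistic Substance Quality Index (PSQI) with an
    accompanying confidence metric, mapped over uniform spatial grids.
    Regulatory bounds default to the Russian SanPiN 1.2.3685-21 drinking-water
    standards but any per-parameter bounds table can be supplied.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
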