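Package: vesiclekit
Title: Single-Vesicle TIRF Fusion and Clustering Analysis with a Synthetic
    Microscope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-vesicle total internal reflection
    fluorescence (TIRF) assays of SNARE-mediated membrane fusion and
    alpha-synuclein-induced vesicle clustering. Provides diffraction-limited
    spot detection and intensity normalization, single-versus-cluster
    classification from intensity histograms, stepwise dequenching (content
    mixing) event detection in per-spot traces, post-synchronized fusion
    kinetics with bi-exponential fits, clustering-assay counting with
    Student's t-test condition comparisons, and a ground-truth synthetic
    movie generator emulating the experimental conditions so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
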