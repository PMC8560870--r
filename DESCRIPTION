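Package: megwave
Title: Space-Frequency-Time MEG Markers for Three-Class Dementia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a bimodal magnetoencephalography (MEG)
    classification pipeline for discriminating Alzheimer's disease, mild
    cognitive impairment and healthy controls. Region-of-interest sensor
    groups are stacked into time-by-sensor "MEG images", decomposed with a
    two-dimensional wavelet packet transform, and summarised into compact
    marker vectors (terminal horizontal-detail nodes across three levels).
    Magnetometer and gradiometer modalities are classified separately
    (3-nearest-neighbour and quadratic Bayes normal classifier) and combined
    by product-rule score fusion at the participant level. Includes a
    synthetic Elekta-306-style resting-state generator with controllable
    class structure, leakage-free leave-one-participant-out and hybrid
    LOO-MCRS cross-validation schemes, a Monte Carlo random-subsampling
    baseline, and Kruskal-Wallis/Holm significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
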