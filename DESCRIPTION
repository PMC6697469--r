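Package: coelute
Title: Co-Fractionation Interactome Prediction and Complex Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns protein co-fractionation profiles (SEC-PCP-SILAC style
    fraction-by-protein ratio tables) into a scored binary interactome and a
    set of predicted protein complexes, and quantifies the biological
    plausibility of both. Includes profile cleaning and Gaussian elution-peak
    fitting, pairwise similarity features, a cross-validated Gaussian naive
    Bayes classifier with precision-based interaction scores, two-stage
    ClusterONE + MCL complex detection evaluated by the maximum matching
    ratio, rewired-network and random-complex null models, and a synthetic
    co-fractionation data generator with known ground truth for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
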