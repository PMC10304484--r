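Package: tailmix
Title: Two-Phase Resampling for Long-Tailed Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating long-tailed image
    classification benchmarks and for training classifiers under severe
    class imbalance. Provides two benchmark constructions (a Pareto-style
    rank profile and consumption-frequency scaling from a packaged table
    of 74 U.S. food types), representative head-class undersampling by
    herding with temperature-scaled knowledge distillation to retain the
    removed information, and visual-similarity-aware multi-image CutMix
    oversampling of tail classes. Ships a seeded procedural generator of
    synthetic image datasets with controllable long-tail profiles and
    inter-class visual similarity, so the whole pipeline runs at desk
    scale without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    tibble,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
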