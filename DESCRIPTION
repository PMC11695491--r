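Package: edatox
Title: Effect-Directed Analysis Feature Prioritization and Genotoxicity
    Prediction for Non-Target Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing non-target LC-HRMS features from
    effect-directed analysis (EDA) of complex mixtures such as food-contact
    materials. Implements the four-rule fraction-membership filter cascade
    (parent abundance, fraction/parent ratio, blank exclusion, zone
    exclusivity), in-source fragment grouping from shared MS2 evidence,
    suspect screening by exact monoisotopic mass, fingerprint-based
    genotoxicity classifiers with an any-endpoint activity rule, candidate
    structure ranking with top-decile genotoxicity statistics, and a seeded
    synthetic-study generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    igraph,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
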