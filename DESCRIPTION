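Package: stripakr
Title: Quantitative Analysis of STRIPAK Mutant Phosphoproteomics, Genetic
    Interactions, and Endosomal Shuttling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for three quantitative procedures used to study
    striatin-interacting phosphatase and kinase (STRIPAK) signalling in
    filamentous fungi: differential phospho-regulation calling from iTRAQ
    8-plex reporter-ion tables (channel-sum normalization, replicate-averaged
    log2 ratios, ratio/SD scores with a 2xSD call rule, cross-omic gating
    against the global proteome, site-level aggregation, overlap and motif
    window utilities); multiplicative genetic-interaction analysis of
    vegetative growth rates with one-tailed t-tests; and kymograph track
    analytics for endosomal shuttling (processivity, density, velocity,
    microtubule-inhibition contrast, and dual-channel co-localization).
    Seeded synthetic-data generators reproduce the statistical structure of
    each input so every stage can be exercised and calibrated offline.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
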