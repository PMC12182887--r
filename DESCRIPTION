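Package: paintnnd
Title: Nearest-Neighbor-Distance Analysis of DNA-PAINT Localization Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies membrane receptor-ligand oligomerization and
    co-localization from single-molecule localization microscopy (DNA-PAINT)
    data. Converts localization clouds into precision-weighted protein
    positions, computes first and cross nearest-neighbor distance (NND)
    distributions, simulates complete-spatial-randomness (CSR) nulls at
    measured densities, summarises clustering with the delta-area statistic,
    compares treatment conditions by one-way ANOVA, and separates membrane
    layers axially from 3D data. Includes a ground-truth scene generator
    (monomers, dimers, oligomer clusters, vesicles, partial labeling) and a
    DNA-PAINT localization forward model so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    withr,
    ggplot2,
    generics,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
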