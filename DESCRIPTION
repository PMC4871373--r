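Package: scmcycle
Title: Standard-Component Models of the Budding Yeast Cell Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and simulates "standard component" models (SCMs) of protein
    regulatory networks, in which species are partitioned into slowly varying
    totals governed by synthesis and degradation (class 1), rapidly modified
    activities governed by soft-Heaviside switching kinetics (class 2), and
    tightly bound complexes resolved algebraically with max/min rules
    (class 3). Ships two worked instantiations for budding yeast: a model of
    the Start transition (with a multisite-phosphorylation reference model)
    and a model of the full cell-division cycle with event rules, asymmetric
    division and an in-silico mutant screen. A chemical-Langevin layer adds
    protein noise and mRNA-inherited noise for single-cell simulations, and
    analysis helpers provide saddle-node bifurcation scans, lineage and
    population statistics, size-control regression and growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
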