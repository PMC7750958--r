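Package: idroute
Title: Reconstructing Transposon Invasion Routes from Internal-Deletion Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based forward simulation of DNA-transposon invasions with
    internal deletions (IDs), piRNA-cluster trapping and 1D stepping-stone
    migration, together with the analysis pipeline that reconstructs invasion
    routes from ID fingerprints: breakpoint clustering with positional tolerance,
    Jost's D distance matrices treating each ID and the full-length element as
    alleles of one locus, BIONJ trees, bootstrap majority-rule consensus,
    shared-split tree comparison against the expected invasion route, random-tree
    nulls with a conjugate Beta-binomial posterior, scaled PCA and Mantel tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    withr
Config/testthat/edition: 3
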