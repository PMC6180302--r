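Package: depickr
Title: Target Deconvolution of Phenotypic Small-Molecule Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational target deconvolution of phenotypic
    small-molecule suppression screens. Implements circular (Morgan/ECFP-style)
    fingerprinting of molecular graphs with Tanimoto similarity and duplicate
    collapsing across compound libraries; ligand-based target prediction by
    k-nearest-neighbour similarity search with Laplacian-corrected naive Bayes
    scoring and cross-validated precision calibration; hypergeometric target
    enrichment among screen actives with Benjamini-Hochberg false discovery
    rate control; permutation tests for the significance of shared actives
    between two screens; Gene Ontology biological-process enrichment with
    is_a annotation propagation; and the auxiliary summary statistics of
    screening studies (hit rates, pooled two-sample t-tests and one-way ANOVA
    with Tukey comparisons from group summaries, comparative-Ct fold changes,
    protein-network summaries, and MeSH D27 bucketing). Seeded synthetic-data
    generators emulate the screen structure end to end so every stage is
    testable offline.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
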