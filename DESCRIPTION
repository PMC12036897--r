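Package: invcooccur
Title: Segregation Distortion and Genotype-Level Co-Occurrence of Chromosomal Inversions in F2 Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for detecting single-locus segregation
    distortion and pairwise genotype-level epistasis (coupling/repulsion)
    among unlinked chromosomal inversions segregating in F2 crosses.
    Provides Williams-corrected G goodness-of-fit tests with a sequential
    gametic/zygotic selection-mode diagnosis, omnibus 3x3 contingency tests
    with Monte-Carlo p-values and standardized-residual post hocs,
    zero-centered co-occurrence indexes from community ecology (centered
    Jaccard/Tanimoto with a bootstrap test, and the affinity score as the
    log-odds maximizer of the noncentral hypergeometric likelihood with an
    exact test), a survival-rate contingency-table simulator for method
    calibration, replicated G heterogeneity tests across crosses, and
    network/motif analysis of the resulting interaction structure with a
    degree-preserving rewiring null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
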