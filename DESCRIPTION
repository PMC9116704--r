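Package: phylimp
Title: Random-Forest Imputation of Phylogenetic Distance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes missing entries in phylogenetic pairwise distance
    matrices with an iterative random-forest scheme guided by phylogenetic
    criteria. Each column of the matrix is regressed on the others with a
    bespoke ensemble of sum-of-squared-residual regression trees, the
    partially imputed matrix is symmetrised by selecting among triangular
    candidate solutions with least-squares or minimum-evolution tree fit,
    and iteration stops when the phylogenetic fit no longer improves.
    Includes neighbor-joining tree construction, Robinson-Foulds scoring,
    a synthetic benchmark generator based on random additive matrices,
    and a benchmark runner that measures topological recovery across
    missing-data percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
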