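Package: clonefuse
Title: Integration of Clone Proportions and Clone Trees Across Mutation
    Feature Classes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor clones are routinely deconvolved from bulk DNA sequencing
    separately for single-nucleotide variants (SNVs) and copy-number
    aberrations (CNAs), yielding two incompatible clonal decompositions of
    the same tumor. clonefuse integrates the two: given clone proportion
    matrices (and optionally rooted clone trees) for each feature class, it
    computes an integrated set of paired clones, their proportions, and a
    refined clone tree by exact combinatorial optimization. It implements
    the Parsimonious Clone Integration problem (minimize the number of
    paired clones subject to marginal consistency) and the Parsimonious
    Clone Tree Integration problem (among refinements of the two input
    trees, minimize the total absolute proportion correction), together
    with brute-force oracles, a ground-truth simulator with tunable noise,
    3-partition reduction generators for adversarial instances, and
    evaluation metrics (clone recall, parent-child distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
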