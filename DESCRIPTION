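Package: pathnetgwas
Title: Pathway- and Network-Oriented Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-GWAS pathway analysis from summary statistics: p-value
    filtering and functional weighting of SNPs, aggregation into gene scores
    (max/sum of 1-df chi-squared statistics), Fisher's combined test across
    datasets, Monte-Carlo-calibrated active-subnetwork search on
    protein-protein interaction networks, DIAMOnD-style hypergeometric seed
    expansion, hypergeometric pathway over-representation with multiple-testing
    correction, Cohen's-kappa pathway co-membership networks with MCODE-style
    clustering, and normalized-mutual-information comparison of module sets
    across datasets. Includes a seeded synthetic-data generator that plants
    known modules and pathways so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
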