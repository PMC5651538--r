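Package: senopharm
Title: Systems-Pharmacology Prioritization of Anti-Aging Indications for
    Natural Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Curates aging-associated genes (AAGs) across five model
    organisms via ortholog mapping, builds filtered drug-target interaction
    (DTI) networks from bioactivity records, densifies them by resource
    diffusion on a substructure-drug-target tripartite network, and scores
    each compound's anti-aging indication with a genome-wide permutation
    statistic, Z-score, and Benjamini-Hochberg correction. Includes a
    synthetic-data generator with planted ground truth for end-to-end
    recovery testing, hypergeometric closed-form oracles for the
    permutation null, Tanimoto k-medoids compound clustering, and
    GraphML/TSV network exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    cluster,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
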