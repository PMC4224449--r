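Package: fibronet
Title: Discovery of Disease-Relevant Interaction Network Modules from
    Chemical-Exposure Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-toxicology pipeline that discovers disease-relevant
    protein-interaction network modules from chemical-exposure gene
    expression compendia. Starting from probe-level log2 intensities over
    many exposure conditions, the pipeline builds a gene-by-condition
    log-ratio matrix, identifies differentially expressed genes per
    condition with the rank-product statistic and permutation-based FDR,
    finds co-expressed gene clusters by hierarchical clustering with a
    dynamic tree cut, scores clusters and network modules by their mean
    Z-score activation in a designated disease-condition subset, extracts
    maximally connected subnetworks with a node-exception budget, detects
    possibly overlapping network modules by maximal-clique agglomeration
    with extended modularity, prioritizes modules by gene-set enrichment
    and activation, and assesses significance, robustness and specificity
    with permutation null models and leave-one-quarter-out resampling. A
    synthetic-data module generates DrugMatrix-like studies with planted
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
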