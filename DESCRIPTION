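Package: canenet
Title: Gene Co-Expression Network Analysis of Nitrogen Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for gene co-expression network
    analysis of nitrogen-response transcriptomes in a two-genotype,
    two-nitrogen-level, four-leaf-segment factorial design. Covers
    differential-expression screening with exclusive set intersections,
    hard-thresholded Pearson correlation networks, from-scratch Markov
    clustering (MCL) into co-expression modules, module eigengenes and
    Spearman module-trait screening with Bonferroni control, spectral-density
    Kullback-Leibler comparison against Erdos-Renyi, small-world and
    scale-free null models, joint degree/betweenness hub calling, and
    Fisher's-exact overrepresentation tests. Ships a synthetic-data generator
    that plants co-expression modules, trait couplings and annotation
    enrichments with known ground truth, so every stage is verifiable
    without raw sequencing data.
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
    Matrix,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
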