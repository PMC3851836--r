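Package: cregnet
Title: Combinatorial TF-miRNA Gene Regulatory Network Inference from
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers combinatorial gene regulatory networks involving both
    transcription factors (TFs) and microRNAs (miRNAs) by integrating
    putative regulation libraries (TF-gene, TF-miRNA, miRNA-gene edge
    lists) with gene expression data. One engine analyses
    miRNA-perturbed gene expression (MPGE) log-ratio datasets: it tests
    global target degradation with a one-sided Kolmogorov-Smirnov test,
    refines degraded targets with per-gene empirical tail probabilities,
    screens candidate TFs by univariate regression and selects mediating
    TFs by stepwise multivariate regression, yielding a two-layer
    network centred on the perturbed miRNA. A second engine analyses
    parallel miRNA/mRNA expression matrices with per-target stepwise
    linear models to build a genome-wide three-edge-type network.
    Topology tools rank vertices and edges by degree and betweenness,
    detect co-regulating regulator pairs with one-sided Fisher tests,
    and enumerate, count and assess the significance of the eighteen
    typed triple-vertex motifs via degree-preserving network
    randomisation. Seeded simulators with planted ground truth support
    validation end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
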