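Package: wgsimpute
Title: Simulation-Driven Evaluation of Whole-Genome Sequence Imputation
    Accuracy and Downstream Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating reference-panel genotype imputation to
    whole-genome sequence in structured (multi-breed) populations. Provides
    a seeded synthetic-population generator (recombination-mosaic descent
    from a shared ancestral haplotype pool, SNP-array ascertainment,
    annotation-class labelling, heritable phenotypes, low-fidelity genomic
    regions), a Li-Stephens haplotype-copying imputation engine producing
    allele dosages, most-likely genotypes and a Minimac-style per-variant
    R-squared quality statistic, cross-validation masking and per-variant
    empirical accuracy assessment with MAF-band, R-squared-bin, 1-Mb-window,
    annotation-class and per-chromosome summaries, and an R-squared-stratified
    genomic-prediction experiment using a four-component BayesR mixture model
    fitted by Gibbs sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
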