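Package: MicrobiomeNormBench
Title: Benchmarking Normalization Methods for Cross-Study Quantitative
    Phenotype Prediction from Metagenomic Counts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how normalization choices affect cross-study
    prediction of quantitative phenotypes (for example body-mass index) from
    taxon-by-sample metagenomic count tables. Provides a Dirichlet-multinomial
    simulator of heterogeneous study pairs covering population effects,
    ComBat-style location-scale batch effects and divergent phenotype models;
    reference implementations of 21 normalization methods spanning scaling
    (TSS, UQ, MED, CSS, TMM, RLE, GMPR), compositional (CLR), transformation
    (LOG, AST, STD, Rank, Blom, NPN, logCPM, VST) and batch-correction
    (QN, FSQN, BMC, linear-model, ComBat) families with a train/test protocol
    that keeps the test set out of the training-set normalization; a seeded
    random-forest regression stage scored by RMSE with 1..K method ranking;
    and a community-statistics audit (Shannon diversity, Bray-Curtis
    dissimilarity, PCoA, marginal PERMANOVA, Wilcoxon shift tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    vegan
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    limma,
    sva,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
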