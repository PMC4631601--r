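Package: microgwas
Title: Genome-Wide Association Analysis of Gut Microbiome Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for mapping host genetic effects on gut
    microbial relative abundance in family-structured cohorts. Implements
    taxon count preprocessing (read subsampling, prevalence filtering,
    rank-based inverse normal transformation, correlated-taxon pruning,
    season averaging and alpha diversity), genotype quality control with an
    exact Hardy-Weinberg test, genomic-relationship kinship matrices, a
    univariate linear mixed model with per-predictor likelihood-ratio tests
    and REML chip-heritability (PVE) estimation, Storey q-value FDR control,
    permutation tests for heritability-GWAS overlap, and candidate-tissue
    identification by fold enrichment of top association signals in
    DNase-hypersensitivity peaks calibrated with full GWAS permutations.
    A synthetic-data module generates family genotypes with known kinship,
    compositional taxon counts with planted genetic and covariate effects,
    and tissue-specific open-chromatin peak sets, so every stage can be
    validated against a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vegan,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
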