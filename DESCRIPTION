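Package: FPsieve
Title: Machine-Learning Detection of False Positive SNVs in GATK Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A trainable, interpretable filter for false positive single
    nucleotide variant (SNV) calls. Combines GATK HaplotypeCaller quality
    metrics (QD, FS, SOR, MQ, DP, GQ, rank-sum tests) with genomic features
    (GC and CpG-island window content, ancestral/derived allele state,
    transition/transversion class, amino-acid transition probabilities) in a
    cost-sensitive random forest trained with duplicate-aware, class-stratified
    cross-validation. Provides VCF input/output with per-variant false-positive
    scores, sensitivity-targeted decision thresholds, permutation feature
    importance, additive per-variant explanations, and a synthetic call-set
    generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    ranger,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: VariantDetection, Classification, Sequencing, SNP
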