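Package: tagfun
Title: Post-GWAS Dissection of a Disease Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting a GWAS-associated disease locus down to a
    candidate functional variant: fixed-effects inverse-variance meta-analysis
    of per-study odds ratios with heterogeneity statistics and genomic control,
    genotype quality-control filters and additive allele-dosage logistic
    association tests (including conditional tests), trans-ethnic fine-mapping
    via linkage-disequilibrium statistics and a constrained haplotype-resampling
    null for tag-SNP consistency, a genotype-dependent transcription-factor to
    target-gene coexpression likelihood-ratio test with inverse-variance pooling
    of correlation differences, and position-weight-matrix and splice-enhancer
    allele scoring. A synthetic-data generator emulates haplotype panels with
    target LD, case-control genotypes under an additive log-odds model,
    genotype-dependent coexpression data and null summary statistics, so every
    stage runs without access to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
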