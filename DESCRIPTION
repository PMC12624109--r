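Package: meqaxis
Title: Discovery and Plausibility Screening of SNP-Methylation-Expression-Risk Axes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated methylation quantitative trait locus (meQTL)
    analysis pipeline for case-control cancer susceptibility studies. Starting
    from tumor/normal CpG methylation matrices, the package calls consensus
    differentially methylated sites across datasets, intersects them with
    tissue and blood meQTL summary tables, filters candidate SNP-CpG-gene
    triples by methylation-expression correlation, expression fold change,
    minor allele frequency and linkage-disequilibrium pruning, tests each
    surviving SNP for disease association under an additive logistic model,
    and classifies every axis with a sign-consistency biological-plausibility
    rule set built on the negative-regulation model of promoter methylation.
    A synthetic cohort generator with Hardy-Weinberg genotypes, LD blocks and
    planted axes makes every stage testable without restricted data, and a
    co-methylation burden module quantifies the joint dosage effect of
    co-hypermethylated CpG sites on target gene expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
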