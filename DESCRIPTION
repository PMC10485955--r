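Package: triomics
Title: Multi-Omics Association Mapping of DNA Methylation, Genotype and
    Metabolite Data in Type 2 Diabetes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis pipeline for blood multi-omics studies of
    type 2 diabetes: two-way discovery/replication epigenome-wide association
    testing of CpG methylation against disease status, kinship-aware
    methylation quantitative trait locus (meQTL) mapping with a polygenic
    mixed model and score test, metabolome-wide association with Bonferroni
    discovery/replication, heterogeneity-filtered inverse-variance
    meta-analysis of CpG-metabolite associations, two-sample Mendelian
    randomization from summary statistics (Wald ratio, single-SNP maximum
    likelihood and inverse-variance weighting), and assembly of a tripartite
    SNP-CpG-metabolite network with shrinkage partial-correlation metabolite
    edges. A fully parameterized synthetic-cohort generator with recorded
    ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, Metabolomics, GenomeWideAssociation,
    NetworkInference, Software
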