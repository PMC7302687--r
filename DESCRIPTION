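Package: gtpanel
Title: GT-seq SNP Panel Design, Amplicon QC and Population Assignment
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs optimized amplicon (GT-seq) SNP panels from
    population-scale ddRAD genotype matrices and deploys them for
    invasive-species forensics. Implements the candidate-locus filter
    cascade (call rate, minor allele frequency, observed heterozygosity,
    per-species depth, one SNP per RADtag, tag-offset window), per-locus
    Weir-Cockerham theta for all population pairs, genomic spacing pruning
    and top-K panel selection with species-diagnostic loci, amplicon
    read-count QC and allele-ratio genotype calling, cross-method and
    replicate concordance metrics, Rannala-Mountain Bayesian population
    assignment, reference-anchored projected PCA and DAPC-style species
    classification, plus a two-species island-model simulator
    (Balding-Nichols) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    MASS,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
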