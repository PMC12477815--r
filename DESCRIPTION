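Package: NMDeff
Title: Individual-Level Quantification of Nonsense-Mediated mRNA Decay Efficiency
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the efficiency of nonsense-mediated mRNA decay (NMD) at
    the level of individual samples from bulk RNA-seq derived counts. Two
    complementary negative-binomial regression estimators are provided: the
    endogenous target gene (ETG) method, which contrasts NMD-target transcripts
    against paired same-gene control transcripts, and the allele-specific
    expression (ASE) method, which contrasts mutant against wild-type RNA allele
    counts at germline premature termination codons (PTCs). Supporting
    machinery includes transcript-model parsing and NMD-feature annotation
    (upstream ORFs, 3'UTR exon-junction complexes, 3'UTR GC content),
    rule-based classification of PTCs as NMD-triggering or NMD-evading,
    per-PTC efficiency scores with variability randomization tests,
    tissue-level randomization statistics (ITNVD and TND) with empirical-FDR
    calibration, sparse-PCA copy-number signatures with genomic
    autocorrelation tuning, and a fully deterministic synthetic-cohort
    generator with a ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, Transcriptomics, Regression, CopyNumberVariation
Collate: 
    'AllClasses.R'
    'ase.R'
    'cna.R'
    'etg.R'
    'io.R'
    'nb-glm.R'
    'nmd-features.R'
    'pnmdeff.R'
    'ptc.R'
    'simulate.R'
    'tissue-tests.R'
    'transcript-model.R'
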