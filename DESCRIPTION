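Package: scarsig
Title: Mutational Signature Refitting and Genomic Scar Scores for
    Tumor/Normal Whole-Genome Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream statistical analysis of annotated short-variant and
    allele-specific copy-number data from tumor/normal whole-genome
    sequencing studies of breast cancer. Builds SBS96 and ID83 mutation
    catalogs from MAF-style variant tables, refits them as mixtures of
    fixed COSMIC-style reference signatures by expectation-maximization,
    computes the three genomic scar scores (HRD-LOH, large-scale
    transitions, telomeric allelic imbalances) with homologous
    recombination deficiency classification, calculates tumor mutational
    burden and somatic mutational prevalence, and provides cohort-level
    statistics: aggregated allele-frequency comparison against reference
    populations, panel-versus-WGS concordance, HRD-versus-signature
    correlation, and clinicopathological summary tables. A synthetic-data
    module generates genomes, mutation sets with known signature mixtures,
    and segment profiles with planted scar events so every stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
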