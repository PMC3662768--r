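Package: proteovenom
Title: Integrative Transcriptome-Proteome Identification of Venom Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies secreted venom proteins from a non-genome-sequenced
    organism by integrating a de novo transcriptome with shotgun proteomics
    data. Transcripts are expression-filtered at a TPM threshold (with an EM
    quantifier for ambiguous read counts), translated in all six reading
    frames into a stop-to-stop ORF search database, and promoted to venom
    protein identifications by a probability/length/charge peptide filter
    cascade with razor assignment of shared peptides, spectral counting and
    coverage statistics. Validation statistics include a heuristic secretion
    signal predictor with chi-square enrichment, binned BLAST E-value
    distribution comparisons, conserved-domain set overlaps and hypergeometric
    GO term enrichment with Bonferroni correction. A fully ground-truthed
    synthetic scenario generator makes every stage testable without external
    data.
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
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Transcriptomics, MassSpectrometry, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'enrichment.R'
    'peptides.R'
    'pipeline.R'
    'proteovenom-package.R'
    'synthetic.R'
    'transcriptome.R'
    'translation.R'
    'utils.R'
    'validation.R'
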