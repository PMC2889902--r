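Package: DlabArray
Title: Oligo Microarray Construction and Expression Profiling for the
    European Sea Bass
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to build and analyse a two-probe 60mer oligonucleotide
    microarray platform for a non-model fish transcriptome: EST clustering
    into unique transcripts under overlap/identity criteria, 3'-proximal
    probe-pair selection with composition and cross-hybridisation screens,
    homology-based annotation with GO slim roll-ups and model-organism
    identifier mapping, spike-in-guided normalisation and array quality
    control, permutation-based SAM differential expression with
    probe-to-transcript aggregation and a tissue-dilution fold-change
    model, orientation-based natural antisense transcript inference,
    GO over-representation against a custom array background, and
    efficiency-corrected qPCR cross-validation. A synthetic-data module
    generates every input with known ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Microarray, Normalization, DifferentialExpression,
    GeneExpression, QualityControl, Annotation
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
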