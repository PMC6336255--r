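Package: lncflow
Title: Discovery, Classification and ceRNA Network Analysis of Long
    Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable downstream pipeline for long non-coding RNA
    (lncRNA) transcriptomics in multi-tissue RNA-seq designs: a
    stepwise novelty filter cascade over assembled transcripts
    (length, read coverage, overlap with known coding genes,
    similarity to known lncRNAs, coding potential), positional
    classification of lncRNAs against their nearest partner gene into
    six genic/intergenic classes, RPKM quantification and
    expression-presence sets, a fold-change and FDR differential
    expression screen, co-expression based cis-target prediction
    within a genomic window, exact hypergeometric term enrichment, and
    construction of competing endogenous RNA (lncRNA-miRNA-mRNA)
    networks from shared miRNA-binding evidence and expression-trend
    consistency.  Includes a fully deterministic synthetic-study
    generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation-io.R'
    'cerna.R'
    'cis.R'
    'classify.R'
    'diffexpr.R'
    'discovery.R'
    'enrich.R'
    'expression.R'
    'interval-ops.R'
    'pipeline.R'
    'simulate.R'
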