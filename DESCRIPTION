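Package: mirswim
Title: Small RNA-Seq miRNA Profiling and Novel miRNA Discovery for
    Two-Library Exercise Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline for
    two-library (treatment versus control) miRNA profiling, built around
    the design of pooled-RNA rat brain exercise studies. Provides adapter
    trimming and read filtering to clean 18-30 nt unique tags,
    perfect-match genome mapping, priority-based non-miRNA annotation,
    known miRNA identification against a miRBase-style mature reference
    with isomiR tolerance, novel miRNA prediction by hairpin folding with
    a six-criterion acceptance rule (MFE, MFEI, single-arm mature,
    2-nt 3' overhang duplex geometry, mismatch and bulge limits, minimum
    read support), TPM normalisation with Audic-Claverie two-library
    differential expression, and 2-of-3 target-prediction consensus
    voting. A synthetic-data generator plants hairpin loci, known miRNAs,
    fold changes and contaminant reads so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
biocViews: Sequencing, SmallRNA, GeneExpression, DifferentialExpression,
    Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
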