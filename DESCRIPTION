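Package: mirdevel
Title: Small-RNA miRNA Discovery, Developmental Expression and Target
    Validation Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of a plant small-RNA analysis
    workflow: adapter trimming and read triage of small-RNA libraries,
    known/conserved miRNA cataloguing with three-group transcriptome
    classification, novel miRNA prediction by hairpin secondary-structure
    criteria (folded with ViennaRNA's RNAfold), median-reference regression
    normalization with one-way ANOVA differential expression, degradome
    (PARE) cleavage-site validation with category 0-4 classification and
    T-plot export, and weighted coexpression network analysis with
    topological overlap, module eigengenes and hypergeometric set
    enrichment. A synthetic-data module generates every input the pipeline
    consumes (reference bundle, stage-structured FASTQ libraries, degradome
    tags, Ct tables) with recorded ground truth, so the whole workflow is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
SystemRequirements: ViennaRNA (RNAfold, RNAeval on PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
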