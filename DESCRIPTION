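Package: tilclone
Title: Clonal Architecture of Tumor-Infiltrating T Cells from TCR
    Repertoire, Single-Cell and Spatial Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of the clonal architecture of
    tumor-infiltrating T cells. Reads bulk TRB-CDR3 repertoires
    (ImmunoSEQ-export or AIRR Rearrangement dialects) and computes
    Shannon-entropy clonality and repertoire similarity; tracks
    clonotypes across tumor, normal adjacent tissue and blood and
    classifies their tissue-distribution patterns; annotates CDR3s
    against specificity databases and control-donor libraries and
    detects public clonotypes and convergent nucleotypes; groups CDR3s
    into predicted-specificity clusters by shared interior motifs;
    pairs TRA/TRB chains per cell, classifies clone sizes, lineages and
    phenotypes from expression, and reconciles single-cell with bulk
    clonal frequencies; profiles T-cell density against signed distance
    to the tumor border from multiplex-IHC cell tables. A synthetic
    cohort generator with full ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    mgcv,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
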