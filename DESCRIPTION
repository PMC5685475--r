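Package: coneswitch
Title: Detection and Regulatory Analysis of a Developmental Gene-Expression Switch in Cone Photoreceptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a postnatal gene-expression switch in developing
    mouse cone photoreceptors. Covers RPKM normalisation with skewness-guided
    expression thresholding, switch detection by day-level principal component
    analysis and pre/post fold changes with a native negative-binomial
    likelihood-ratio test, permutation-based transcription-factor and pathway
    enrichment, exon-intron split analysis separating transcriptional from
    post-transcriptional regulation, differential chromatin accessibility from
    ATAC-seq peak counts with CTCF-motif stratification, and an elastic-net model
    relating accessibility change to motif content. A synthetic-data module
    generates all inputs with known ground truth so every stage is testable
    end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    glmnet,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
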