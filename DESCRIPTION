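Package: cometh
Title: Co-Methylation-Aware Quantification of RRBS Data and Paired DMR Calling
Version: 0.9.0
Authors@R:
    person("cometh", "developers", email = "cometh@example.org", role = c("aut", "cre"))
Description: Read-level quantification of CpG methylation from reduced
    representation bisulfite sequencing (RRBS), implementing the run-length
    weighted Wemics estimator alongside the classical Meanm, CHALM and CAMDA
    rates; a de-novo caller for differentially methylated regions in matched
    tumor/normal designs using binary segmentation scored by an exact Wilcoxon
    signed-rank test; downstream statistics linking methylation to gene
    expression and regulatory annotation (promoter/enhancer correlation,
    CpG-island context, DMR-gene classification, transcription-factor motif
    activity scores and variance-explained models); and a synthetic epiallele
    simulator with planted DMRs and a correlated expression layer for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicAlignments,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
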