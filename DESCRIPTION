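Package: tailscan
Title: 3' RACE Terminal Profiling, Proximity-Labeling Proteomics Screening,
    and Telomere Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the 3' end of a noncoding RNA from 3'
    RACE deep sequencing (linker trimming, anchored read acceptance,
    template-maximal boundary calling, and classification of termini into
    genomically encoded ends, mono-adenylated ends, and oligo(A) tails),
    for screening proximity-labeling (BioID-style) proteomics quantification
    tables (unique-peptide filtering, iBAQ-based FOT normalization,
    replicate correlation QC, and a fold-change/t-test enrichment screen),
    and for reducing common quantitative assays (comparative-CT relative
    quantification, qPCR-based relative telomerase activity, and
    densitometric mean terminal restriction fragment length). Includes
    seeded synthetic-data generators with planted ground truth for every
    input, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
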