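Package: tfnominate
Title: Nominating Upstream Transcription Factors from Paired Chromatin
    Accessibility and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-omics screen that nominates a direct upstream
    transcription factor (TF) of a target gene from paired ATAC-seq
    accessibility and RNA-seq expression matrices over the same samples:
    nearest-TSS peak annotation with promoter categories, selection of
    accessible promoter peaks overlapping the target locus, a Pearson
    screen of TF expression against peak accessibility, and ChIP-seq
    overlap support.  Ships the supporting computations of such a study
    (single-sample gene-set enrichment scoring of immune signatures,
    Spearman screens of receptor families against infiltration scores,
    Kaplan-Meier/log-rank survival analysis with a maximally selected
    optimal cutpoint, Cox model fitting with Harrell concordance) and a
    synthetic-data generator with a planted TF-peak-gene regulatory
    chain for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
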