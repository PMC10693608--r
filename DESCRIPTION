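Package: infantvax
Title: Longitudinal Vaccine-Response Transcriptomics and Serology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal blood transcriptome studies of
    infant vaccination. Implements quality control and counts-per-million
    normalization of single-cell UMI matrices, per-cell gene-set (interferon,
    inflammation, cytotoxicity) module scores with binned-control background
    correction, per-subcluster Wilcoxon rank-sum differential expression with
    exact small-sample p-values, gene two-dimension augmentation (G2DA) scanning
    of joint expression-level and expressing-cell-fraction increases, stream-plot
    data preparation, bulk modular transcriptional fingerprints, serology
    seroprotection and responder ranking, and cell-frequency/score association
    summaries. Ships seeded synthetic-data generators (single-cell counts, bulk
    intensities, serology titers) with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
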