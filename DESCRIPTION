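Package: epinorm
Title: Normalisation Robustness for Methylation-Array Epigenetic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the choice of methylation-array
    normalisation strategy affects epigenetic score (EpiScore) projection
    when a cohort is normalised on its own versus jointly with a reference
    cohort. Provides a synthetic two-cohort array simulator with Type I/II
    probe chemistry, batch-specific background and dye bias; sixteen
    normalisation strategies (raw, systematic quantile-normalisation
    variants, SWAN, BMIQ, peak-based correction, Noob, functional
    normalisation and subset quantile normalisation); the DMRSE, GCOSE and
    Seabird quality metrics with rank aggregation; elastic-net EpiScore
    training and projection; and separate-versus-joint robustness
    statistics (median absolute score difference, correlation with
    phenotype, incremental R-squared, percentile shifts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    limma,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC
Config/testthat/edition: 3
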