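Package: cnconcord
Title: Concordance of Copy-Number Variation and Differential Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pan-cancer style analysis of the dosage relationship between
    somatic copy-number variation and differential gene expression. Computes
    diploid-referenced mRNA Z-scores from GISTIC-style discrete copy-number
    calls (or PICNIC-style absolute copy number with average genome ploidy),
    classifies per-(gene, sample) variation tendencies (amplified/deleted x
    up-/downregulated), quantifies per-gene concordance with Spearman rank
    correlation and median-Z linear fits, identifies amplified-and-upregulated
    (AUG) and deleted-and-downregulated (DDG) genes via a concordance-ratio
    rule with thresholds calibrated from reference oncogene and tumor
    suppressor lists, and stratifies overall survival by tendency status with
    Kaplan-Meier curves and log-rank tests. Includes a synthetic paired
    copy-number/expression/clinical cohort generator for testing and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
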