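Package: niptscreen
Title: Noninvasive Prenatal Aneuploidy Screening from Shallow cfDNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of fetal trisomies 13, 18 and 21 from shallow
    whole-genome sequencing of maternal plasma cell-free DNA. Counts
    uniquely mapped reads per chromosome from SAM/BAM, estimates the
    fetal fraction from the short/long fragment-size ratio, computes
    three chromosome-representation statistics (Z-score, Trisomy Ratio
    and GC-corrected Fractional Genomic Representation) against a
    euploid reference panel, calibrates per-score cut-offs by ROC
    analysis (Youden's J) and classifies samples with configurable
    score-combination rules. Includes a seeded generator of synthetic
    maternal-plasma sequencing data (multinomial chromosome counts with
    GC bias, mixture fragment-length distributions, SAM output) with
    known ground truth, and cohort-level sensitivity/specificity
    evaluation that distinguishes false positives, false negatives and
    trisomic samples called for the wrong chromosome.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
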