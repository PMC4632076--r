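Package: niptcnv
Title: Maternal CNV-Aware Noninvasive Prenatal Aneuploidy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-depth workflow for noninvasive prenatal testing (NIPT) of
    fetal trisomy 13, 18 and 21 from shallow whole-genome sequencing of
    maternal plasma cell-free DNA. Counts unique reads in 100-kb bins,
    corrects GC and mappability bias, scores chromosomes against a euploid
    reference panel, detects maternal copy-number variants by segmentation
    of overlapping-window Z-scores, removes their effect on chromosome
    coverage through an analytic coverage coefficient, and filters false
    positives by the discrepancy between fetal fractions estimated from
    chromosome X and from the aneuploid chromosome. Includes a Poisson
    plasma simulator for validating the workflow on synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
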