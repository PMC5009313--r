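Package: bsamarker
Title: Bulked Segregant Analysis Marker Discovery on Subtracted Diversity Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of trait-linked DNA markers from subtracted genomic DNA
    microarrays hybridised with phenotype-contrasted DNA bulks (bulked segregant
    analysis). Provides readers for quantified array-scan tables and sample
    sheets, signal-to-noise quality control with spike-in normalisation,
    per-bulk feature fingerprints, per-feature two-group statistics (Fisher's
    ratio, Levene-gated pooled/Welch t-tests), two-group stepwise discriminant
    function analysis with Wilks' lambda entry/removal and Fisher
    classification functions, three-way intersection of the selection criteria,
    genomic context annotation of candidate markers under a
    centimorgan-to-base-pair window, and a seeded allele-dosage simulator that
    generates bulk-hybridisation data with a planted linked marker for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
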