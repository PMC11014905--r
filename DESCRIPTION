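Package: elnrisk
Title: ELN 2017/2022 Genetic Risk Stratification for Acute Myeloid Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic rule engines for the European LeukemiaNet (ELN)
    2017 and 2022 genetic risk classifications of acute myeloid leukemia,
    an ISCN karyotype feature extractor, and from-first-principles survival
    statistics (Kaplan-Meier, log-rank, Cox proportional hazards with Efron
    ties, Harrell's concordance with paired comparison, censoring-adjusted
    net reclassification improvement, and the Mantel-Byar time-dependent
    transplant analysis) used to compare the two stratifications. Includes
    a synthetic-cohort generator whose genotype archetypes reproduce a
    published reclassification structure and whose outcomes follow
    calibrated group-specific exponential hazards, plus an end-to-end
    validation pipeline with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
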