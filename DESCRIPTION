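Package: hearvar
Title: Family-Based Variant Prioritization and Hearing-Language Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline linking genetic variation in hearing genes to language
    outcomes, built around a discovery-family design with population-cohort
    follow-up. Provides pedigree allele-sharing scans for dominantly inherited
    haplotypes, dual-caller copy-number consensus by reciprocal overlap, a
    step-wise variant prioritization cascade, derived audiometric and language
    phenotypes with case/control classification, additive and gene-by-hearing
    interaction regression, a variance-component (SKAT-style) gene-based test,
    Fisher/FDR enrichment statistics, prepulse-inhibition attenuation scoring,
    ultrasonic-vocalization syllable filtering, and seeded synthetic-data
    generators that emulate every input so the whole pipeline is testable
    end to end without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
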