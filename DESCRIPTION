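Package: preopanemia
Title: Laboratory-Guided Classification and Management of Preoperative Anemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for laboratory-guided preoperative anemia management in
    elective surgery cohorts. Classifies anemia etiology from the soluble
    transferrin receptor / log ferritin index together with reticulocyte
    hemoglobin content (the Thomas plot), provides the ferritin/transferrin-
    saturation comparator grid used in the NATA guideline, derives iron/ESA
    therapy recommendations with study-eligibility filters, and summarises
    cohorts: anemia prevalence, hemoglobin courses, transfusion and cost
    accounting. Includes from-scratch exact nonparametric tests (exact
    Mann-Whitney U, Fisher exact, Monte-Carlo exact chi-square), Bland-Altman
    and reliability statistics for paired point-of-care versus reference
    hemoglobin measurements, and a seeded synthetic-cohort generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
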