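Package: bleedabr
Title: Bleed-Diary Adjudication and Annualized Bleeding Rate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing patient-reported bleed and medication
    diaries from people with hemophilia A. Links bleeds to subsequent
    treatments under calendar-day sharing rules, classifies bleeds as
    treated or untreated, optionally applies the ISTH 72-hour collapsing
    rule, classifies joint bleeds under cohort-specific symptom or
    location definitions, and estimates annualized bleeding rates (ABRs)
    both by direct calculation and from negative-binomial regression with
    a follow-up offset, including an intraindividual paired model with a
    participant random intercept. Includes a seeded synthetic-diary
    generator and exact count-fixture builders for validating every stage
    without access to patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmmTMB,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
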