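Package: menoderive
Title: Rule-Based Derivation of Menopausal Status from Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives menopausal status from coded questionnaire responses in
    cohort studies of women aged 45 and over. Implements a step-by-step
    algorithm: categorisation of interventions that can mask menopause
    (menopausal hormone therapy, hysterectomy, bilateral oophorectomy), a
    seven-category detailed derived status combining self-report with
    intervention timing, data-driven estimation of the baseline-age threshold
    above which women are highly likely to be post-menopausal (reference,
    conservative and least-conservative methods), and consolidation to four
    categories (post-, peri-, pre-menopause, unknown) with age-based
    re-classification of masked or unknown status. Includes a seeded synthetic
    cohort generator with latent truth for validation, cross-tabulation and
    reclassification reporting, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
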