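Package: acroface
Title: Craniofacial Morphometrics and Discriminant Screening for Acromegaly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based craniofacial morphometrics pipeline for studying
    facial changes in acromegaly. Ingests per-subject 3D facial landmarks
    (optionally with a triangulated surface mesh), aligns each head to the
    Frankfort Horizontal plane, evaluates a 58-parameter catalog of linear,
    angular, index, plane-distance, curve and cross-section semi-perimeter
    measurements, runs a sex-by-disease univariate screening battery
    (Levene, two-way ANOVA, post-hoc pooled t-tests, Bonferroni control),
    and classifies patient versus control cohorts with a from-scratch
    linear discriminant analysis under leave-one-out cross-validation with
    a label-permutation null. A seedable synthetic-cohort generator
    (feature-table and landmark level) emulates the matched case-control
    study design so every stage is testable without restricted clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
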