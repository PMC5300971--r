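Package: nkstrat
Title: Unsupervised NK-Cell Maturation Profiling from Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An unsupervised analysis pipeline for five-marker natural
    killer (NK) cell cytometry panels (CD56, CD16, NKG2A, NKG2C, CD57).
    Events are pre-gated to the NK compartment, clustered per sample with
    seeded finite Gaussian (or Student-t) mixture models selected by BIC
    and ICL, and the pooled cluster centroids are percentile-rescaled,
    hierarchically metaclustered and annotated into named NK maturation
    populations. Per-patient population-frequency matrices are used to
    stratify a cohort into maturation-profile groups, which are compared
    with tie-corrected Kruskal-Wallis and Dunn's post-hoc rank tests.
    A synthetic-cohort generator reproduces the statistical structure of
    a primary-HIV-infection cohort (patient groups with distinct NK
    maturation profiles and matching clinical metadata) so the whole
    pipeline can be exercised and validated without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
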