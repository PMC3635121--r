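Package: blastovar
Title: Positional Variability Analysis of Blastoderm Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing of per-nucleus Drosophila blastoderm expression
    records into integrated antero-posterior profiles; quadratic-spline
    extraction of expression-domain features (peaks, half-maximum
    boundaries, widths, temporal shifts, even-skipped stripe-7 pattern
    classes); and embryo-to-embryo variability statistics (directional
    Student t-tests on mean positions, median-based Levene
    (Brown-Forsythe) tests on positional variance, Bonferroni-corrected
    test grids) for comparing canalisation between genotypes. Includes a
    seeded synthetic-cohort generator with wild-type-like and
    tailless-like presets so the entire pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
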