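Package: fodmapr
Title: FODMAP Food-Composition Databases and Dietary Intake Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building provenance-tracked food composition databases
    extended with FODMAP (fermentable oligo-, di-, monosaccharide and polyol)
    content, deriving profiles for composite foods by recipe calculation,
    computing per-person and population FODMAP intake from multi-day food
    diaries (including the excess-fructose rule and total-FODMAP accounting),
    ranking the most commonly eaten and highest-content FODMAP sources,
    sample-size planning for intake surveys, and an energy-based
    under-reporting screen. Includes a synthetic dietary-survey generator
    with closed-form ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
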