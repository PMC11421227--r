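Package: dairymod
Title: Diet Modeling of Milk Substitution and Addition Scenarios in
    School-Aged Children
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling the nutritional impact of dairy
    interventions on 24-hour dietary recall data from school-aged
    children: conversion of recall items to daily nutrient intakes,
    energy-outlier exclusion, dairy serving computation, counterfactual
    substitution of current milk with a fortified milk beverage, tiered
    addition of milk up to recommended servings, usual-intake estimation
    from a single recall day via an external within- to between-person
    variance ratio, and population prevalence of nutrient inadequacy
    (EAR cut-point, full-probability method for iron, AMDR and UL
    classification). Includes a synthetic survey generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
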