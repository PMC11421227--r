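test_that("per-child totals follow grams/100 x composition and flag consumers", {
  foods <- tibble::tibble(food_code = "F1", energy = 80, protein = 2,
                          carbohydrate = 12, fat = 2, sfa = 1, mufa = 0.5,
                          pufa = 0.3, calcium = 50, phosphorus = 40,
                          iron = 0.5, zinc = 0.4, vitamin_a = 10,
                          vitamin_d = 0, vitamin_c = 1, thiamin = 0.02,
                          riboflavin = 0.05, niacin = 0.4, vitamin_b6 = 0.03,
                          folate = 4, retinol_fraction = 0.5,
                          folic_acid_fraction = 0)
  recall <- tibble::tibble(child_id = "A", age = 6, sex = "F", weight = 18,
                           food_code = "F1", grams = 200,
                           dairy_subtype = NA_character_, is_tea_milk = FALSE)
  cd <- compute_intakes(recall, foods)
  expect_equal(cd$calcium, 100)
  expect_equal(cd$retinol, 200 / 100 * 10 * 0.5)
  expect_false(cd$dairy_consumer)
  expect_equal(cd$servings, 0)

  expect_error(compute_intakes(dplyr::mutate(recall, food_code = "NOPE"),
                               foods), "unknown food code")
  expect_error(compute_intakes(dplyr::mutate(recall, grams = -5), foods),
               "non-negative")
})

test_that("toy-fixture totals equal an independent spreadsheet-style recomputation", {
  for (nm in c("energy", "calcium", "iron", "vitamin_a", "folate")) {
    hand <- hand_totals(toy$recall, toy$foods, nm)
    expect_equal(toy_cd[[nm]], unname(hand[toy_cd$child_id]),
                 tolerance = 1e-12)
  }
  # dairy mass balance: subtype grams sum to the recall's dairy grams
  dairy_rows <- toy$recall[!is.na(toy$recall$dairy_subtype), ]
  hand_dairy <- tapply(dairy_rows$grams, dairy_rows$child_id, sum)
  got <- toy_cd$dairy_g_total[match(names(hand_dairy), toy_cd$child_id)]
  expect_equal(got, as.numeric(hand_dairy))
  sub_cols <- paste0("dairy_g_", dairy_subtypes())
  expect_equal(rowSums(toy_cd[, sub_cols]), toy_cd$dairy_g_total)
})

test_that("tea-with-milk components count as milk", {
  t09 <- toy_cd[toy_cd$child_id == "T09", ]
  expect_true(t09$milk_consumer)
  expect_equal(t09$dairy_g_milk_buffalo, 250)
  expect_equal(t09$servings, 1)
})

test_that("intake computation is linear: disjoint concatenation and gram doubling", {
  surv <- small_survey(60, seed = 17)
  half1 <- surv$recall[surv$recall$child_id <= "C00030", ]
  half2 <- surv$recall[surv$recall$child_id > "C00030", ]
  joint <- compute_intakes(surv$recall, surv$foods)
  apart <- dplyr::bind_rows(compute_intakes(half1, surv$foods),
                            compute_intakes(half2, surv$foods))
  apart <- apart[match(joint$child_id, apart$child_id), ]
  expect_equal(joint$energy, apart$energy)
  expect_equal(joint$dairy_g_total, apart$dairy_g_total)

  doubled <- compute_intakes(dplyr::mutate(surv$recall, grams = grams * 2),
                             surv$foods)
  expect_equal(doubled$calcium, 2 * joint$calcium, tolerance = 1e-12)
  expect_equal(doubled$dairy_g_total, 2 * joint$dairy_g_total)
  expect_equal(mean(joint$dairy_g_total > 0), mean(joint$dairy_consumer))
})

test_that("grams convert to servings at 250 g per serving, full precision", {
  expect_equal(grams_to_servings(250), 1)
  expect_equal(grams_to_servings(0), 0)
  expect_equal(grams_to_servings(145.1), 0.5804)
  expect_equal(round(grams_to_servings(145.1), 1), 0.6)
  expect_error(grams_to_servings(-1), "non-negative")
})

test_that("energy outliers are flagged beyond 3 SD within 1-y age strata", {
  # brute-force oracle on a constructed stratum
  energies <- c(rep(1000, 50), 5000)
  cd <- tibble::tibble(child_id = as.character(seq_along(energies)),
                       age = 6, sex = "M", weight = 20, energy = energies)
  m <- mean(energies); s <- stats::sd(energies)
  oracle <- abs(energies - m) > 3 * s
  expect_true(oracle[51])
  flagged <- flag_energy_outliers(cd)
  expect_equal(flagged$energy_outlier, oracle)

  # identical energies: SD 0, nothing flagged
  same <- tibble::tibble(child_id = as.character(1:10), age = 7, sex = "F",
                         weight = 20, energy = rep(1500, 10))
  expect_false(any(flag_energy_outliers(same)$energy_outlier))

  # a singleton stratum cannot be assessed
  solo <- tibble::tibble(child_id = "x", age = 9, sex = "F", weight = 25,
                         energy = 1500)
  expect_warning(flag_energy_outliers(solo), "stratum")
})

test_that("the fixture's constructed outlier is flagged within a realistic stratum", {
  # the outlier child sits ~4 SD above its age-mates once the stratum is
  # large enough for the 3-SD rule to have power
  set.seed(5)
  background <- tibble::tibble(
    child_id = sprintf("B%03d", 1:80), age = 6, sex = "M", weight = 20,
    energy = stats::rnorm(80, 1100, 200))
  stratum <- dplyr::bind_rows(
    background, toy_cd[toy_cd$child_id == "T08", names(background)])
  flagged <- flag_energy_outliers(stratum)
  expect_true(flagged$energy_outlier[flagged$child_id == "T08"])
  kept <- exclude_energy_outliers(flagged)
  expect_equal(attr(kept, "n_excluded"), 1)
  expect_false("T08" %in% kept$child_id)
})

test_that("dairy adherence categories follow the 2-servings recommendation", {
  expect_equal(as.character(classify_dairy_adherence(c(0, 0.4, 1.7, 2.0, 3))),
               c("none", "<1", "1-1.9", ">=2", ">=2"))
  expect_true(meets_dairy_recommendation(2.0))
  expect_false(meets_dairy_recommendation(1.999))
  expect_error(classify_dairy_adherence(-0.1), "non-negative")
})
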