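test_that("EAR cut-point prevalence counts children below their own EAR", {
  expect_equal(ear_cutpoint_prevalence(c(1, 2, 3), 10), 100)
  expect_equal(ear_cutpoint_prevalence(c(1, 2, 3), 0.5), 0)
  # symmetric continuous intakes around the EAR give ~50%
  set.seed(1)
  x <- rnorm(20000, 100, 15)
  expect_lt(abs(ear_cutpoint_prevalence(x, 100) - 50), 1.5)
  expect_true(is.na(ear_cutpoint_prevalence(c(1, 2), NA_real_)))
  expect_error(ear_cutpoint_prevalence(1:3, -1), "positive")
})

test_that("EAR cut-point agrees with the closed-form log-normal CDF at n = 50000", {
  set.seed(23)
  mu <- log(500); sb <- 0.5
  usual <- rlnorm(50000, mu, sb)
  ear <- 420
  closed <- 100 * plnorm(ear, mu, sb)
  expect_lt(abs(ear_cutpoint_prevalence(usual, ear) - closed), 1)
})

test_that("the requirement distribution anchors its 97.5th percentile at the RNI", {
  for (rni in c(12.6, 17.8)) {
    d <- requirement_distribution(rni)
    expect_lt(abs(plnorm(rni, d$meanlog, d$sdlog) - 0.975), 1e-6)
  }
  expect_error(requirement_distribution(-1), "positive")
})

test_that("full probability prevalence behaves at the extremes and the median", {
  expect_lt(full_probability_prevalence(rep(126, 50), 12.6), 0.01)
  d <- requirement_distribution(12.6)
  at_median <- rep(exp(d$meanlog), 80)
  expect_equal(full_probability_prevalence(at_median, 12.6), 50)
  expect_error(full_probability_prevalence(c(5, 6), c(12.6, NA)), "undefined")
})

test_that("full probability prevalence matches a Monte-Carlo requirement oracle within 0.5 pp", {
  set.seed(31)
  n <- 100
  age <- sample(5:9, n, replace = TRUE)
  rni <- ifelse(age <= 6, 12.6, 17.8)
  usual <- rlnorm(n, log(7), 0.6)
  analytic <- full_probability_prevalence(usual, rni)
  d <- requirement_distribution(rni)
  draws <- 1e5
  mc <- mean(vapply(seq_len(n), function(i) {
    mean(rlnorm(draws, d$meanlog[i], d$sdlog) > usual[i])
  }, numeric(1))) * 100
  expect_lt(abs(analytic - mc), 0.5)
})

test_that("full probability collapses to the EAR cut-point for a degenerate requirement", {
  set.seed(2)
  usual <- rlnorm(500, log(10), 0.5)
  ear <- 12.6
  tight <- full_probability_prevalence(usual, ear * exp(qnorm(0.975) * 1e-6),
                                       sdlog = 1e-6)
  expect_lt(abs(tight - ear_cutpoint_prevalence(usual, ear)), 0.3)
})

test_that("AMDR classification uses Atwater %E with inclusive bounds", {
  # printed example: 31.8 g protein at 1283 kcal is 9.9 %E, below 10-30
  cls <- amdr_classify(31.8, 1283, "protein", 10, 30)
  expect_equal(round(cls$pct_e, 1), 9.9)
  expect_equal(as.character(cls$class), "below")

  at_bound <- amdr_classify(c(35 / 9 * 10), 1000, "fat", 25, 35)
  expect_equal(as.character(at_bound$class), "within")  # inclusive upper
  zero <- amdr_classify(0, 1800, "fat", 25, 35)
  expect_equal(as.character(zero$class), "below")

  mixed <- amdr_classify(c(20, 50, 120), rep(1200, 3), "protein", 10, 30)
  expect_equal(unname(mixed$pct), c(100 / 3, 100 / 3, 100 / 3))
  expect_equal(sum(mixed$pct), 100)
  expect_warning(amdr_classify(c(10, 10), c(1200, 0), "protein", 10, 30),
                 "zero energy")
})

test_that("UL exceedance applies to preformed retinol and folic acid where required", {
  expect_equal(ul_exceedance(c(100, 2000), 900), 50)
  expect_true(is.na(ul_exceedance(c(1, 2), NA_real_)))
  # all-plant vitamin A: zero preformed fraction means zero exceedance
  rae <- c(5000, 8000)
  retinol <- rae * 0
  expect_equal(ul_exceedance(retinol, 900), 0)
  # brute-force count on a synthetic high-retinol diet
  set.seed(3)
  ret <- rlnorm(5000, log(600), 0.5)
  expect_equal(ul_exceedance(ret, 900), 100 * mean(ret > 900))
})

test_that("scenario comparisons report absolute and relative reductions", {
  base <- tibble::tibble(nutrient = c("vitamin_c", "zinc", "niacin"),
                         mean = 1, se = 0.1,
                         pct_below = c(36, 20, 0), pct_above = 0,
                         population = "baseline")
  scen <- dplyr::mutate(base, pct_below = c(5, 20, 0), population = "sub")
  cmp <- compare_scenarios(base, scen)
  expect_equal(cmp$abs_reduction_pp, c(31, 0, 0))
  expect_equal(round(cmp$rel_reduction_pct[1]), 86)
  expect_equal(cmp$rel_reduction_pct[2], 0)
  expect_true(is.na(cmp$rel_reduction_pct[3]))
  # 100% relative reduction iff the scenario prevalence is zero
  scen2 <- dplyr::mutate(base, pct_below = c(0, 20, 0))
  expect_equal(compare_scenarios(base, scen2)$rel_reduction_pct[1], 100)
  expect_error(compare_scenarios(base, scen[c(2, 1, 3), ]), "same nutrients")
})

test_that("adequacy summaries produce bounded percentages and sensible flags", {
  surv <- small_survey(800, seed = 29)
  cd <- compute_intakes(surv$recall, surv$foods)
  usual <- adjust_usual_intakes(cd)
  s <- adequacy_summary(usual, refs_tbl)
  expect_setequal(s$nutrient, nutrient_names())
  pct <- c(s$pct_below, s$pct_above)
  expect_true(all(pct[!is.na(pct)] >= 0 & pct[!is.na(pct)] <= 100))
  # nutrients with no reference report NA, never silent zero
  expect_true(is.na(s$pct_below[s$nutrient == "sfa"]))
  # iron row comes from the full probability method on RNIs
  rni <- resolve_reference_field(refs_tbl, "iron", usual$age, usual$sex, "rni")
  expect_equal(s$pct_below[s$nutrient == "iron"],
               full_probability_prevalence(usual$iron, rni))
})

test_that("prevalence is monotone non-increasing under milk addition for every nutrient", {
  surv <- small_survey(1500, seed = 37)
  cd <- compute_intakes(surv$recall, surv$foods)
  for (mk in c("buffalo", "fortified")) {
    res <- run_scenario(cd, scenario_spec("addition", mk), milks_tbl)
    for (nm in nutrient_names()) {
      ear <- resolve_ear(refs_tbl, nm, cd$age, cd$sex, cd$weight)
      if (all(is.na(ear))) next
      p0 <- ear_cutpoint_prevalence(cd[[nm]], ear)
      p1 <- ear_cutpoint_prevalence(res$population[[nm]], ear)
      expect_lte(p1, p0 + 1e-9)
    }
  }
})
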