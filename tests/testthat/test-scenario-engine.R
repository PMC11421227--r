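test_that("eligibility: substitution takes milk consumers minus fortified consumers; addition takes <2 servings", {
  sub <- select_eligible(toy_cd, scenario_spec("substitution"))
  expect_setequal(sub$child_id, c("T01", "T02", "T03", "T04", "T05", "T09"))
  add <- select_eligible(toy_cd, scenario_spec("addition", "buffalo"))
  # includes dairy non-consumers, excludes the >=2 servings child
  expect_true(all(c("T07", "T08") %in% add$child_id))
  expect_false("T05" %in% add$child_id)

  # eligibility arithmetic at survey scale: milk consumers minus those
  # already consuming fortified milk
  n <- 5842
  flags <- tibble::tibble(
    child_id = as.character(seq_len(n)),
    milk_consumer = seq_len(n) <= 4950,
    fortified_consumer = seq_len(n) <= 89,
    servings = 0)
  expect_equal(nrow(select_eligible(flags, scenario_spec("substitution"))),
               4861)
})

test_that("substitution replaces milk volume-by-volume with linear nutrient deltas", {
  eligible <- select_eligible(toy_cd, scenario_spec("substitution"))
  out <- substitute_milk(eligible, milks_tbl)
  # dairy grams preserved exactly
  expect_equal(out$dairy_g_total, eligible$dairy_g_total)
  # all non-fortified milk moved to fortified
  expect_true(all(out$dairy_g_milk_buffalo == 0))
  expect_true(all(out$dairy_g_milk_cow == 0))

  # hand-computed from the two composition rows: T05 drinks 550 g cow milk
  cow <- milks_tbl[milks_tbl$milk == "cow", ]
  fort <- milks_tbl[milks_tbl$milk == "fortified", ]
  before <- eligible[eligible$child_id == "T05", ]
  after <- out[out$child_id == "T05", ]
  expect_equal(after$calcium,
               before$calcium + 5.5 * (fort$calcium - cow$calcium))
  expect_equal(after$iron, before$iron + 5.5 * (fort$iron - cow$iron))

  # delta is linear in grams: 135 g buffalo shifts by 1.35 x (fort - buf)
  buf <- milks_tbl[milks_tbl$milk == "buffalo", ]
  one <- eligible[eligible$child_id == "T01", ]  # 100 g buffalo
  d100 <- substitute_milk(one, milks_tbl)$vitamin_c - one$vitamin_c
  expect_equal(d100, 1.0 * (fort$vitamin_c - buf$vitamin_c))

  # a child with no milk is unchanged
  none <- toy_cd[toy_cd$child_id == "T07", ]
  expect_equal(substitute_milk(none, milks_tbl)$energy, none$energy)
})

test_that("the tiered addition rule reproduces all bands and the cap binds first", {
  expect_equal(tier_addition(0.4), 2.0)
  expect_equal(tier_addition(0.7), 1.5)
  expect_equal(tier_addition(1.0), 1.0)
  expect_equal(tier_addition(1.7), 0.5)
  expect_equal(tier_addition(2.3), 0.0)
  expect_equal(tier_addition(0.4, cap_servings = 1), 1.0)
  expect_equal(tier_addition(c(0, 0.49, 0.5, 1.49, 1.5, 1.99, 2)),
               c(2, 2, 1.5, 1, 0.5, 0.5, 0))
  expect_error(tier_addition(-0.2), "non-negative")
})

test_that("every treated child lands in [2, 2.5) servings under the uncapped rule", {
  # independent enumeration oracle over a fine servings grid
  grid <- seq(0, 1.99, by = 0.01)
  oracle <- function(s) {
    if (s < 0.5) 2 else if (s < 1.0) 1.5 else if (s < 1.5) 1 else 0.5
  }
  added <- vapply(grid, oracle, numeric(1))
  expect_equal(tier_addition(grid), added)
  post <- grid + added
  expect_true(all(post >= 2 & post < 2.5))
})

test_that("addition updates grams, servings and nutrients consistently", {
  add <- select_eligible(toy_cd, scenario_spec("addition", "buffalo"))
  out <- apply_addition(add, "buffalo", milks_tbl, cap_servings = 2)
  buf <- milks_tbl[milks_tbl$milk == "buffalo", ]
  # dairy increases by exactly 250 g per added serving
  expect_equal(out$dairy_g_total - add$dairy_g_total,
               250 * out$added_servings)
  expect_true(all(out$servings >= 2 & out$servings < 2.5))
  # child at 1.2 servings gains one serving of buffalo milk
  i <- which(add$child_id == "T03")
  expect_equal(out$added_servings[i], 1)
  expect_equal(out$energy[i], add$energy[i] + 2.5 * buf$energy)

  # a child at exactly 2 servings is not eligible and would gain nothing
  expect_equal(tier_addition(2.0), 0)

  # idempotence: a second uncapped application adds nothing
  twice <- apply_addition(out[, setdiff(names(out), "added_servings")],
                          "buffalo", milks_tbl, cap_servings = 2)
  expect_true(all(twice$added_servings == 0))
  expect_equal(twice$energy, out$energy)
})

test_that("the capped variant tops children up by at most one serving", {
  add <- select_eligible(toy_cd, scenario_spec("addition", "fortified", 1))
  out <- apply_addition(add, "fortified", milks_tbl, cap_servings = 1)
  expect_true(all(out$added_servings <= 1))
  expect_true(all(out$dairy_g_total - add$dairy_g_total <= 250 + 1e-12))
})

test_that("run_scenario transforms eligible children and leaves the rest untouched", {
  res <- run_scenario(toy_cd, scenario_spec("addition", "buffalo"), milks_tbl)
  pop <- res$population
  expect_equal(pop$child_id, toy_cd$child_id)
  untouched <- toy_cd$servings >= 2
  expect_equal(pop$energy[untouched], toy_cd$energy[untouched])
  expect_true(all(pop$servings >= 2))

  # fortified consumers are excluded from substitution but not addition
  sub_el <- select_eligible(toy_cd, scenario_spec("substitution"))
  add_el <- select_eligible(toy_cd, scenario_spec("addition", "fortified"))
  expect_false("T06" %in% sub_el$child_id)
  expect_true("T06" %in% add_el$child_id)
})
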