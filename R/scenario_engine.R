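#' Declare a dairy-modeling scenario
#'
#' Two counterfactual interventions are supported. `substitution`
#' replaces all currently consumed non-fortified milk (buffalo, cow,
#' goat — including the tea-milk component) volume by volume with
#' fortified milk, among milk consumers who do not already consume
#' fortified milk. `addition` tops up children consuming < 2 dairy
#' servings/d with the chosen milk according to a tiered rule so they
#' reach the recommendation, optionally capped per child (the capped
#' variant adds at most 1 serving/d).
#'
#' @param kind "substitution" or "addition".
#' @param milk Milk kind to add or substitute in ("fortified",
#'   "buffalo", ...).
#' @param cap_servings For addition: maximum servings added per child
#'   (2 for the main scenario, 1 for the capped variant).
#' @return List with class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("substitution", "addition"),
                          milk = "fortified", cap_servings = 2) {
  kind <- match.arg(kind)
  if (cap_servings <= 0) stop("cap_servings must be positive", call. = FALSE)
  structure(list(kind = kind, milk = milk, cap_servings = cap_servings),
            class = "scenario_spec")
}

#' Select children eligible for a scenario
#'
#' Substitution applies to milk consumers excluding those already
#' consuming fortified milk; addition applies to every child consuming
#' fewer than 2 dairy servings/d (dairy non-consumers included).
#'
#' @param childday Child-day table with consumer flags computed.
#' @param spec A [scenario_spec()].
#' @return The eligible subset of `childday`.
#' @export
select_eligible <- function(childday, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$kind == "substitution") {
    childday[childday$milk_consumer & !childday$fortified_consumer, ]
  } else {
    childday[childday$servings < serving_rule()$recommended_lo, ]
  }
}

#' Substitute current milk with fortified milk, volume by volume
#'
#' For every non-fortified milk subtype a child consumes (g grams), the
#' nutrient total changes by g/100 x (fortified - subtype composition);
#' total dairy grams are preserved exactly and non-milk items are
#' untouched. Preformed retinol and folic acid move with the milk's
#' fractions.
#'
#' @param childday Child-day rows to transform (typically the eligible
#'   subset from [select_eligible()]).
#' @param milks Milk composition table from [load_milks()].
#' @return Transformed child-day table.
#' @export
substitute_milk <- function(childday, milks) {
  nut <- nutrient_names()
  fort <- milk_composition(milks, "fortified")
  fort_vec <- as.numeric(fort[1, nut])
  out <- childday
  for (kind in c("buffalo", "cow", "goat")) {
    col <- paste0("dairy_g_milk_", kind)
    g <- out[[col]]
    if (all(g == 0)) next
    src <- milk_composition(milks, kind)
    src_vec <- as.numeric(src[1, nut])
    delta <- outer(g / 100, fort_vec - src_vec)
    out[, nut] <- out[, nut] + delta
    out$retinol <- out$retinol + (g / 100) *
      (fort$vitamin_a * fort$retinol_fraction -
         src$vitamin_a * src$retinol_fraction)
    out$folic_acid <- out$folic_acid + (g / 100) *
      (fort$folate * fort$folic_acid_fraction -
         src$folate * src$folic_acid_fraction)
    out$dairy_g_milk_fortified <- out$dairy_g_milk_fortified + g
    out[[col]] <- 0
  }
  neg <- which(as.matrix(out[, nut]) < -1e-9, arr.ind = TRUE)
  if (length(neg) > 0) out[, nut][out[, nut] < 0] <- 0
  out$fortified_consumer <- out$dairy_g_milk_fortified > 0
  out
}

#' Tiered milk addition rule
#'
#' Servings of milk added to reach the 2 servings/d recommendation,
#' piecewise on exact (unrounded) current servings: below 0.5 servings
#' add 2; 0.5-0.9 add 1.5; 1-1.4 add 1; 1.5-1.9 add 0.5; at or above 2
#' add nothing. Band labels are read as half-open intervals of a
#' one-decimal display ([0.5, 1.0) etc.), which guarantees every
#' treated child reaches at least 2 servings. The result is clipped to
#' the per-child cap (the capped variant uses 1 serving).
#'
#' @param servings Current dairy servings/d (>= 0), vectorised.
#' @param cap_servings Maximum servings added per child.
#' @return Servings of milk to add.
#' @export
tier_addition <- function(servings, cap_servings = 2) {
  if (any(servings < 0, na.rm = TRUE)) {
    stop("servings must be non-negative", call. = FALSE)
  }
  tier <- ifelse(servings < 0.5, 2,
          ifelse(servings < 1.0, 1.5,
          ifelse(servings < 1.5, 1,
          ifelse(servings < 2.0, 0.5, 0))))
  pmin(tier, cap_servings)
}

#' Apply a tiered milk addition to child-day records
#'
#' Adds `tier_addition(servings, cap) * 250` grams of the chosen milk
#' to each row: nutrient totals, retinol/folic acid, subtype grams and
#' servings are all updated. Children already at >= 2 servings are
#' unchanged.
#'
#' @param childday Child-day rows (typically the addition-eligible
#'   subset).
#' @param milk Milk kind to add ("buffalo" or "fortified").
#' @param milks Milk composition table.
#' @param cap_servings Per-child cap on added servings.
#' @return Transformed child-day table with an `added_servings` column.
#' @export
apply_addition <- function(childday, milk, milks, cap_servings = 2) {
  comp <- milk_composition(milks, milk)
  nut <- nutrient_names()
  add_sv <- tier_addition(childday$servings, cap_servings)
  add_g <- add_sv * serving_rule()$grams_per_serving
  out <- childday
  out[, nut] <- out[, nut] + outer(add_g / 100, as.numeric(comp[1, nut]))
  out$retinol <- out$retinol +
    (add_g / 100) * comp$vitamin_a * comp$retinol_fraction
  out$folic_acid <- out$folic_acid +
    (add_g / 100) * comp$folate * comp$folic_acid_fraction
  col <- paste0("dairy_g_milk_", milk)
  if (!col %in% names(out)) {
    stop(sprintf("unknown milk kind '%s'", milk), call. = FALSE)
  }
  out[[col]] <- out[[col]] + add_g
  out$dairy_g_total <- out$dairy_g_total + add_g
  out$servings <- grams_to_servings(out$dairy_g_total)
  out$dairy_consumer <- out$dairy_g_total > 0
  out$milk_consumer <- rowSums(out[, paste0("dairy_g_", milk_subtypes())]) > 0
  out$fortified_consumer <- out$dairy_g_milk_fortified > 0
  out$added_servings <- add_sv
  out
}

#' Run a scenario over a whole population
#'
#' Applies eligibility selection and the scenario transformation,
#' returning the full population with eligible rows transformed and
#' ineligible rows untouched.
#'
#' @param childday Full child-day table.
#' @param spec A [scenario_spec()].
#' @param milks Milk composition table.
#' @return List with `population` (all children, transformed where
#'   eligible), `eligible` (transformed eligible subset) and
#'   `n_eligible`.
#' @export
run_scenario <- function(childday, spec, milks = load_milks()) {
  eligible <- select_eligible(childday, spec)
  transformed <- if (spec$kind == "substitution") {
    substitute_milk(eligible, milks)
  } else {
    apply_addition(eligible, spec$milk, milks, spec$cap_servings)
  }
  pop <- childday
  keep <- !pop$child_id %in% eligible$child_id
  pop <- dplyr::bind_rows(pop[keep, ], transformed[, names(pop)])
  pop <- pop[match(childday$child_id, pop$child_id), ]
  list(population = pop, eligible = transformed,
       n_eligible = nrow(eligible))
}
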