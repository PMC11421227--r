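#' Nutrients tracked by the pipeline
#'
#' The analysis tracks total energy plus 18 nutrients per child per day.
#' These names are the canonical column names of every nutrient table in
#' the package (recall totals, food compositions per 100 g, usual intakes).
#'
#' @return Character vector of nutrient column names. `energy` is kcal;
#'   `protein`, `carbohydrate`, `fat`, `sfa`, `mufa`, `pufa` are g;
#'   `calcium`, `phosphorus`, `iron`, `zinc`, `vitamin_c`, `thiamin`,
#'   `riboflavin`, `niacin`, `vitamin_b6` are mg; `vitamin_a` is ug RAE,
#'   `vitamin_d` is ug, `folate` is ug DFE.
#' @export
nutrient_names <- function() {
  c("energy", "protein", "carbohydrate", "fat", "sfa", "mufa", "pufa",
    "calcium", "phosphorus", "iron", "zinc",
    "vitamin_a", "vitamin_d", "vitamin_c",
    "thiamin", "riboflavin", "niacin", "vitamin_b6", "folate")
}

#' @rdname nutrient_names
#' @details `tracked_fractions()` names the two derived intake columns
#'   carried alongside the nutrient vector: `retinol` (preformed retinol,
#'   ug — the quantity the vitamin A upper level applies to) and
#'   `folic_acid` (synthetic folic acid, ug — the quantity the folate
#'   upper level applies to).
#' @export
tracked_fractions <- function() c("retinol", "folic_acid")

#' Dairy subtypes recognised in recall data
#'
#' Subtype tags on recall rows; `milk_*` tags count as milk (tea-with-milk
#' is emitted as a tagged milk component). One serving of milk is 250 g.
#'
#' @return Character vector of dairy subtype tags.
#' @export
dairy_subtypes <- function() {
  c("milk_buffalo", "milk_cow", "milk_goat", "milk_fortified",
    "yogurt", "ice_cream", "dairy_dessert", "milkshake")
}

#' @rdname dairy_subtypes
#' @export
milk_subtypes <- function() {
  c("milk_buffalo", "milk_cow", "milk_goat", "milk_fortified")
}

#' Serving rule for dairy
#'
#' One serving of milk is 250 g; national dietary guidelines recommend
#' 2-3 servings of dairy per day, and children below 2 servings/d are
#' considered not meeting the recommendation.
#'
#' @return List with `grams_per_serving`, `recommended_lo`, `recommended_hi`.
#' @export
serving_rule <- function() {
  list(grams_per_serving = 250, recommended_lo = 2, recommended_hi = 3)
}

#' General Atwater energy-conversion factors (kcal/g)
#'
#' Used to express macronutrient intake as a percentage of energy (%E)
#' for AMDR classification.
#'
#' @return Named numeric vector (protein 4, carbohydrate 4, fat 9).
#' @export
atwater_factors <- function() c(protein = 4, carbohydrate = 4, fat = 9)

# internal: assert a data frame carries all nutrient columns
check_nutrient_cols <- function(df, what = "table") {
  missing <- setdiff(nutrient_names(), names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing nutrient column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
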