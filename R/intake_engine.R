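#' Convert grams of dairy to servings per day
#'
#' One serving of milk is 250 g. Servings are kept at full precision
#' internally; round only at reporting so that tier boundaries of the
#' addition rule are never distorted.
#'
#' @param grams Dairy grams per day (>= 0), vectorised.
#' @return Servings per day.
#' @export
grams_to_servings <- function(grams) {
  if (any(grams < 0, na.rm = TRUE)) {
    stop("dairy grams must be non-negative", call. = FALSE)
  }
  grams / serving_rule()$grams_per_serving
}

#' Compute per-child daily nutrient intakes from a recall table
#'
#' Sums every consumed item's contribution (grams / 100 x per-100 g
#' composition) to one total nutrient vector per child per day, and
#' accumulates dairy grams per subtype (milk including the tea-milk
#' component, yogurt, ice cream, dairy desserts, milkshakes). Also
#' carries preformed retinol and folic acid (composition amount times
#' the food's `retinol_fraction` / `folic_acid_fraction`), the
#' quantities the vitamin A and folate upper levels apply to.
#'
#' @param recall Tibble with columns `child_id`, `age`, `sex`, `weight`,
#'   `food_code`, `grams`, `dairy_subtype`, `is_tea_milk`.
#' @param foods Tibble with `food_code`, per-100 g nutrient columns and
#'   the two fraction columns.
#' @return A "child-day" tibble: one row per child with nutrient totals,
#'   `retinol`, `folic_acid`, per-subtype dairy grams (`dairy_g_*`),
#'   `dairy_g_total`, `servings`, and consumer flags (`dairy_consumer`,
#'   `milk_consumer`, `fortified_consumer`).
#' @export
compute_intakes <- function(recall, foods) {
  check_nutrient_cols(foods, "food composition table")
  if (any(recall$grams < 0, na.rm = TRUE)) {
    stop("recall grams must be non-negative", call. = FALSE)
  }
  unknown <- setdiff(unique(recall$food_code), foods$food_code)
  if (length(unknown) > 0) {
    stop(sprintf("unknown food code(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  nut <- nutrient_names()
  idx <- match(recall$food_code, foods$food_code)
  comp <- as.matrix(foods[idx, nut])
  contrib <- comp * (recall$grams / 100)
  retinol <- contrib[, "vitamin_a"] * foods$retinol_fraction[idx]
  folic <- contrib[, "folate"] * foods$folic_acid_fraction[idx]

  base <- tibble::tibble(child_id = recall$child_id)
  totals <- rowsum(cbind(contrib, retinol = retinol, folic_acid = folic),
                   group = recall$child_id)
  ids <- rownames(totals)

  # dairy grams per subtype
  subs <- dairy_subtypes()
  dg <- matrix(0, length(ids), length(subs),
               dimnames = list(ids, paste0("dairy_g_", subs)))
  is_dairy <- !is.na(recall$dairy_subtype)
  if (any(is_dairy)) {
    dsum <- rowsum(recall$grams[is_dairy],
                   group = paste(recall$child_id[is_dairy],
                                 recall$dairy_subtype[is_dairy], sep = "\r"))
    key <- do.call(rbind, strsplit(rownames(dsum), "\r", fixed = TRUE))
    dg[cbind(match(key[, 1], ids),
             match(paste0("dairy_g_", key[, 2]), colnames(dg)))] <- dsum[, 1]
  }

  kids <- unique(recall[, c("child_id", "age", "sex", "weight")])
  kids <- kids[match(ids, kids$child_id), ]
  rownames(totals) <- NULL
  rownames(dg) <- NULL
  out <- dplyr::bind_cols(kids, tibble::as_tibble(totals),
                          tibble::as_tibble(dg))
  out$dairy_g_total <- unname(rowSums(dg))
  out$servings <- grams_to_servings(out$dairy_g_total)
  out$dairy_consumer <- out$dairy_g_total > 0
  milk_cols <- paste0("dairy_g_", milk_subtypes())
  out$milk_consumer <- rowSums(out[, milk_cols]) > 0
  out$fortified_consumer <- out$dairy_g_milk_fortified > 0
  out$energy_outlier <- NA
  tibble::as_tibble(out)
}

#' Flag energy-intake outliers within 1-y age strata
#'
#' A child is flagged when its energy intake lies more than 3 standard
#' deviations from the mean of its 1-y age stratum (5, 6, 7, 8, 9 y).
#' Mean and SD are computed in a single pass per stratum (the rule is
#' not re-applied after exclusion). Strata with fewer than two children
#' have no defined SD; nothing is flagged there and a warning is given.
#'
#' @param childday Child-day table from [compute_intakes()].
#' @return The table with `energy_outlier` filled in.
#' @export
flag_energy_outliers <- function(childday) {
  age <- floor(childday$age)
  flag <- rep(FALSE, nrow(childday))
  for (a in unique(age)) {
    i <- which(age == a)
    if (length(i) < 2) {
      warning(sprintf("age stratum %d has < 2 children; no outlier flagging",
                      a), call. = FALSE)
      next
    }
    m <- mean(childday$energy[i])
    s <- stats::sd(childday$energy[i])
    if (s > 0) flag[i] <- abs(childday$energy[i] - m) > 3 * s
  }
  childday$energy_outlier <- flag
  childday
}

#' @rdname flag_energy_outliers
#' @description `exclude_energy_outliers()` drops flagged children (the
#'   exclusion applied before all downstream analyses) and reports the
#'   count.
#' @export
exclude_energy_outliers <- function(childday) {
  if (all(is.na(childday$energy_outlier))) {
    childday <- flag_energy_outliers(childday)
  }
  kept <- childday[!childday$energy_outlier, ]
  attr(kept, "n_excluded") <- sum(childday$energy_outlier)
  kept
}

#' Classify adherence to the dairy recommendation
#'
#' Children consuming no dairy, or fewer than 2 servings/d, do not meet
#' the 2-3 servings/d recommendation. Categories are `none`, `<1`,
#' `1-1.9` and `>=2` on exact (unrounded) servings; 2.0 is inclusive.
#'
#' @param servings Servings per day (>= 0), vectorised.
#' @return Factor with levels `none`, `<1`, `1-1.9`, `>=2`.
#' @export
classify_dairy_adherence <- function(servings) {
  if (any(servings < 0, na.rm = TRUE)) {
    stop("servings must be non-negative", call. = FALSE)
  }
  cut(servings, breaks = c(-Inf, 0, 1, 2, Inf),
      labels = c("none", "<1", "1-1.9", ">=2"),
      right = FALSE, include.lowest = FALSE) |>
    (\(x) {
      x[servings == 0] <- "none"
      x
    })()
}

#' @rdname classify_dairy_adherence
#' @export
meets_dairy_recommendation <- function(servings) {
  servings >= serving_rule()$recommended_lo
}
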