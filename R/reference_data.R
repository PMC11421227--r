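#' Derive an EAR from a WHO Reference Nutrient Intake
#'
#' For nutrients whose bioavailability in the local diet is low (iron,
#' zinc), the estimated average requirement is back-derived by dividing
#' the WHO RNI by a conversion factor from the WHO/FAO fortification
#' guidelines. The result is rounded to one decimal, the precision at
#' which such reference values are tabulated (zinc: 9.6/1.2 = 8.0 mg/d
#' for ages 5-6 y; 11.2/1.2 = 9.3 mg/d for ages 7-9 y).
#'
#' @param rni WHO Reference Nutrient Intake, nutrient units/d (> 0).
#' @param conversion_factor Dimensionless conversion factor (> 0).
#' @return EAR in the same units as `rni`, rounded to one decimal.
#' @export
ear_from_rni <- function(rni, conversion_factor) {
  if (any(!is.finite(rni)) || any(rni <= 0)) {
    stop("invalid reference: rni must be positive", call. = FALSE)
  }
  if (any(!is.finite(conversion_factor)) || any(conversion_factor <= 0)) {
    stop("invalid reference: conversion_factor must be positive", call. = FALSE)
  }
  round(rni / conversion_factor, 1)
}

#' Load the dietary reference table
#'
#' Reads the packaged reference CSV (EAR, UL, AMDR bounds, EER, WHO RNI
#' and conversion factors by nutrient x age band x sex). Nutrients with
#' an RNI and a conversion factor but no tabulated EAR (zinc) have their
#' EAR derived at load time with [ear_from_rni()]. Age bands follow the
#' reference sources: 5-8 y vs 9 y for most nutrients, 5-6 y vs 7-9 y
#' for iron and zinc. The vitamin A EAR at age 9 is sex-specific.
#'
#' @param path Optional path to an alternative reference CSV with the
#'   same columns; defaults to the table shipped with the package.
#' @return Tibble with one row per nutrient x age band (x sex).
#' @export
load_references <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "references.csv", package = "dairymod")
  }
  refs <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            nutrient = "c", sex = "c", ear_basis = "c",
                            .default = "d"))
  derive <- !is.na(refs$rni) & !is.na(refs$conversion_factor) & is.na(refs$ear)
  refs$ear[derive] <- ear_from_rni(refs$rni[derive],
                                   refs$conversion_factor[derive])
  validate_references(refs)
  refs
}

# internal sanity checks on a reference table
validate_references <- function(refs) {
  with_amdr <- !is.na(refs$amdr_lo) & !is.na(refs$amdr_hi)
  if (any(refs$amdr_lo[with_amdr] >= refs$amdr_hi[with_amdr])) {
    stop("invalid reference: AMDR lower bound must be below upper bound",
         call. = FALSE)
  }
  if (any(refs$ear <= 0, na.rm = TRUE)) {
    stop("invalid reference: EAR must be positive where present", call. = FALSE)
  }
  both <- !is.na(refs$ear) & !is.na(refs$ul) &
    (is.na(refs$ear_basis) | refs$ear_basis == "absolute")
  if (any(refs$ul[both] <= refs$ear[both])) {
    stop("invalid reference: UL must exceed EAR where both present",
         call. = FALSE)
  }
  invisible(refs)
}

#' Look up the reference record for a nutrient, age and sex
#'
#' Resolves the age-band-correct row of the reference table: iron and
#' zinc use the 5-6 vs 7-9 y split, all other nutrients 5-8 vs 9 y; rows
#' marked for one sex only (vitamin A at age 9, energy) are resolved by
#' the child's sex.
#'
#' @param refs Reference table from [load_references()].
#' @param nutrient One nutrient name from [nutrient_names()].
#' @param age_years Age in years, in `[5, 9]` (fractional ages fall in
#'   the band of their completed year).
#' @param sex "M" or "F"; only consulted where the reference is
#'   sex-specific.
#' @return One-row tibble (the reference record).
#' @export
lookup_reference <- function(refs, nutrient, age_years, sex = "F") {
  if (!nutrient %in% nutrient_names()) {
    stop(sprintf("unknown nutrient '%s'", nutrient), call. = FALSE)
  }
  if (!is.finite(age_years) || age_years < 5 || age_years >= 10) {
    stop(sprintf("age %s outside the 5-9 y scope", format(age_years)),
         call. = FALSE)
  }
  age <- floor(age_years)
  hit <- refs[refs$nutrient == nutrient &
                refs$age_lo <= age & age <= refs$age_hi &
                (refs$sex == "all" | refs$sex == sex), , drop = FALSE]
  if (nrow(hit) != 1) {
    stop(sprintf("reference lookup failed for %s, age %d, sex %s",
                 nutrient, age, sex), call. = FALSE)
  }
  hit
}

#' Resolve per-child EARs for one nutrient
#'
#' Vectorised reference resolution: returns each child's EAR given age
#' and sex. The protein EAR is expressed per kg body weight and is
#' multiplied by the child's weight; all other EARs are absolute
#' amounts per day. Returns NA where no EAR is defined (iron, fat).
#'
#' @param refs Reference table.
#' @param nutrient Nutrient name.
#' @param age Vector of ages (years).
#' @param sex Vector of "M"/"F".
#' @param weight Vector of body weights (kg); required for protein.
#' @return Numeric vector of per-child EARs (units/d).
#' @export
resolve_ear <- function(refs, nutrient, age, sex, weight = NULL) {
  ear <- resolve_reference_field(refs, nutrient, age, sex, "ear")
  basis <- refs$ear_basis[refs$nutrient == nutrient][1]
  if (!is.na(basis) && basis == "g_per_kg") {
    if (is.null(weight)) {
      stop("weight required for a per-kg EAR", call. = FALSE)
    }
    ear <- ear * weight
  }
  ear
}

#' @rdname resolve_ear
#' @param field Reference column to resolve ("ul", "rni", "eer", ...).
#' @export
resolve_reference_field <- function(refs, nutrient, age, sex, field = "ul") {
  if (!nutrient %in% nutrient_names()) {
    stop(sprintf("unknown nutrient '%s'", nutrient), call. = FALSE)
  }
  if (any(!is.finite(age) | age < 5 | age >= 10)) {
    stop("age outside the 5-9 y scope", call. = FALSE)
  }
  rows <- refs[refs$nutrient == nutrient, , drop = FALSE]
  agef <- floor(age)
  out <- rep(NA_real_, length(age))
  seen <- rep(0L, length(age))
  for (k in seq_len(nrow(rows))) {
    hit <- rows$age_lo[k] <= agef & agef <= rows$age_hi[k] &
      (rows$sex[k] == "all" | rows$sex[k] == sex)
    out[hit] <- rows[[field]][k]
    seen[hit] <- seen[hit] + 1L
  }
  if (any(seen != 1L)) {
    stop(sprintf("reference lookup failed for %s (no unique age/sex band)",
                 nutrient), call. = FALSE)
  }
  out
}

#' Load milk compositions
#'
#' Reads per-100 g compositions of buffalo, cow, goat and fortified milk
#' from a YAML file. The packaged defaults are synthetic stand-ins drawn
#' from standard food-composition sources (the survey's own appendix
#' values are not publicly printed) and are intended to be overridden
#' with local values where available.
#'
#' @param path Optional path to a YAML file keyed by milk kind; defaults
#'   to the packaged `milks_synthetic.yaml`.
#' @return Tibble, one row per milk kind, nutrient columns per 100 g
#'   plus `retinol_fraction` and `folic_acid_fraction`.
#' @export
load_milks <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "milks_synthetic.yaml",
                        package = "dairymod")
  }
  raw <- yaml::read_yaml(path)
  milks <- dplyr::bind_rows(lapply(names(raw), function(kind) {
    tibble::as_tibble(c(list(milk = kind), raw[[kind]]))
  }))
  check_nutrient_cols(milks, "milk composition table")
  validate_milks(milks)
  milks
}

# internal: non-negativity and Atwater energy consistency (within 15%)
validate_milks <- function(milks) {
  vals <- as.matrix(milks[, nutrient_names()])
  if (any(vals < 0)) {
    stop("milk composition amounts must be non-negative", call. = FALSE)
  }
  atwater <- 4 * milks$protein + 4 * milks$carbohydrate + 9 * milks$fat
  off <- abs(atwater - milks$energy) / pmax(milks$energy, 1e-9)
  if (any(off > 0.15)) {
    stop(sprintf("milk energy inconsistent with Atwater sum for: %s",
                 paste(milks$milk[off > 0.15], collapse = ", ")),
         call. = FALSE)
  }
  invisible(milks)
}

# internal: one milk row as a named nutrient vector per 100 g
milk_composition <- function(milks, kind) {
  row <- milks[milks$milk == kind, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(sprintf("unknown milk kind '%s'", kind), call. = FALSE)
  }
  row
}
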