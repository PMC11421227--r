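#' EAR cut-point prevalence of inadequate intake
#'
#' The fraction of children whose usual intake falls below their
#' estimated average requirement, with age-band- and sex-specific EARs
#' resolved per child before counting.
#'
#' @param usual Usual intakes (units/d).
#' @param ear Per-child EARs (scalar or vector, units/d).
#' @return Percentage in `[0, 100]`, or `NA` when no EAR is defined.
#' @export
ear_cutpoint_prevalence <- function(usual, ear) {
  if (all(is.na(ear))) return(NA_real_)
  if (any(ear <= 0, na.rm = TRUE)) {
    stop("EAR must be positive", call. = FALSE)
  }
  100 * mean(usual < ear)
}

#' Iron requirement distribution anchored at the WHO RNI
#'
#' The RNI covers the needs of 97.5% of a group, so the requirement
#' distribution is anchored with its 97.5th percentile at the RNI. A
#' log-normal family (default log-SD 0.25) captures the right skew of
#' absorbed-iron requirements: `meanlog = log(RNI) - 1.96 * sdlog`.
#'
#' @param rni WHO Reference Nutrient Intake (mg/d) for the age band.
#' @param sdlog Log-scale SD of the requirement distribution.
#' @return List with `meanlog`, `sdlog` (class `requirement_dist`).
#' @export
requirement_distribution <- function(rni, sdlog = 0.25) {
  if (any(rni <= 0) || sdlog <= 0) {
    stop("rni and sdlog must be positive", call. = FALSE)
  }
  structure(list(meanlog = log(rni) - stats::qnorm(0.975) * sdlog,
                 sdlog = sdlog), class = "requirement_dist")
}

#' Full probability method for the prevalence of inadequate iron intake
#'
#' Averages, over children, the probability that a randomly drawn
#' requirement from the child's age-band requirement distribution
#' exceeds the child's usual intake:
#' `100 / n * sum_i P(R_i > y_i)`. Unlike the EAR cut-point, this uses
#' the whole requirement distribution, appropriate for iron whose
#' requirements are markedly skewed.
#'
#' @param usual Usual iron intakes (mg/d), one per child.
#' @param rni Per-child RNI (mg/d), resolved by age band.
#' @param sdlog Log-scale SD of the requirement distribution.
#' @return Percentage in `[0, 100]`.
#' @export
full_probability_prevalence <- function(usual, rni, sdlog = 0.25) {
  if (length(rni) == 1) rni <- rep(rni, length(usual))
  stopifnot(length(rni) == length(usual))
  if (any(is.na(rni))) {
    stop("requirement distribution undefined for some children",
         call. = FALSE)
  }
  dist <- requirement_distribution(rni, sdlog)
  p_exceed <- 1 - stats::plnorm(usual, meanlog = dist$meanlog,
                                sdlog = dist$sdlog)
  100 * mean(p_exceed)
}

#' Classify macronutrient intake against the AMDR
#'
#' Expresses a macronutrient as percent of energy (%E = grams x Atwater
#' factor / energy x 100; protein and carbohydrate 4 kcal/g, fat
#' 9 kcal/g) and classifies each child against inclusive AMDR bounds
#' `[lo, hi]`. Children with zero energy are excluded with a warning.
#'
#' @param grams Macronutrient intake (g/d).
#' @param energy Energy intake (kcal/d).
#' @param macronutrient "protein", "carbohydrate" or "fat".
#' @param lo,hi AMDR bounds in %E.
#' @return List with `pct_e` (per child), `class` (factor below/
#'   within/above) and `pct` (named percentages summing to 100).
#' @export
amdr_classify <- function(grams, energy, macronutrient, lo, hi) {
  fac <- atwater_factors()[[macronutrient]]
  if (is.null(fac)) {
    stop(sprintf("no Atwater factor for '%s'", macronutrient), call. = FALSE)
  }
  ok <- energy > 0
  if (!all(ok)) {
    warning(sprintf("%d children with zero energy excluded from %%E",
                    sum(!ok)), call. = FALSE)
  }
  pct_e <- rep(NA_real_, length(grams))
  pct_e[ok] <- grams[ok] * fac / energy[ok] * 100
  cls <- factor(ifelse(pct_e < lo, "below",
                ifelse(pct_e > hi, "above", "within")),
                levels = c("below", "within", "above"))
  tab <- table(cls[ok])
  list(pct_e = pct_e, class = cls,
       pct = stats::setNames(100 * as.numeric(tab) / sum(ok), names(tab)))
}

#' Percentage of children above the tolerable upper intake level
#'
#' For most nutrients the UL applies to total intake. For vitamin A it
#' applies to preformed retinol only, and for folate to folic acid
#' (from fortification) only — pass those columns as `value`.
#'
#' @param value Per-child intake the UL applies to (total nutrient,
#'   preformed retinol, or folic acid).
#' @param ul Per-child UL (scalar or vector).
#' @return Percentage in `[0, 100]`, `NA` if no UL defined.
#' @export
ul_exceedance <- function(value, ul) {
  if (all(is.na(ul))) return(NA_real_)
  100 * mean(value > ul)
}

#' Summarise population adequacy for every nutrient
#'
#' Builds a per-nutrient table of mean usual intake, SE of the mean,
#' percent below the EAR (full probability method for iron; %E below
#' the AMDR for macronutrients) and percent above the UL (%E above the
#' AMDR for macronutrients; preformed retinol for the vitamin A UL,
#' folic acid for the folate UL).
#'
#' @param childday Child-day table of usual intakes (already adjusted).
#' @param refs Reference table.
#' @param label Population label recorded on every row.
#' @param iron_sdlog Log-SD of the iron requirement distribution.
#' @return Tibble: `nutrient`, `mean`, `se`, `pct_below`, `pct_above`,
#'   `population`.
#' @export
adequacy_summary <- function(childday, refs, label = "baseline",
                             iron_sdlog = 0.25) {
  n <- nrow(childday)
  rows <- lapply(nutrient_names(), function(nm) {
    x <- childday[[nm]]
    mean_x <- mean(x)
    se_x <- stats::sd(x) / sqrt(n)
    rec1 <- lookup_reference(refs, nm, 5, "F")
    pct_below <- NA_real_
    pct_above <- NA_real_
    if (nm == "iron") {
      rni <- resolve_reference_field(refs, nm, childday$age, childday$sex,
                                     "rni")
      pct_below <- full_probability_prevalence(x, rni, iron_sdlog)
    } else if (!is.na(rec1$amdr_lo)) {
      cls <- amdr_classify(x, childday$energy, nm, rec1$amdr_lo, rec1$amdr_hi)
      pct_below <- cls$pct[["below"]]
      pct_above <- cls$pct[["above"]]
    } else if (!is.na(rec1$ear)) {
      ear <- resolve_ear(refs, nm, childday$age, childday$sex,
                         childday$weight)
      pct_below <- ear_cutpoint_prevalence(x, ear)
    }
    ul <- resolve_reference_field(refs, nm, childday$age, childday$sex, "ul")
    if (!all(is.na(ul))) {
      value <- switch(nm,
                      vitamin_a = childday$retinol,
                      folate = childday$folic_acid,
                      x)
      pct_above <- ul_exceedance(value, ul)
    }
    tibble::tibble(nutrient = nm, mean = mean_x, se = se_x,
                   pct_below = pct_below, pct_above = pct_above)
  })
  out <- dplyr::bind_rows(rows)
  out$population <- label
  out
}

#' Compare baseline and scenario adequacy
#'
#' Per nutrient: absolute reduction in percent inadequate
#' (`p0 - p1`, percentage points) and relative reduction
#' (`100 (p0 - p1)/p0`, the form scenario results are quoted in).
#' Relative reduction is undefined (NA) when the baseline prevalence
#' is zero.
#'
#' @param baseline,scenario Summaries from [adequacy_summary()] over
#'   the same nutrients and population.
#' @return Tibble: `nutrient`, `p_baseline`, `p_scenario`,
#'   `abs_reduction_pp`, `rel_reduction_pct`.
#' @export
compare_scenarios <- function(baseline, scenario) {
  if (!identical(baseline$nutrient, scenario$nutrient)) {
    stop("baseline and scenario summaries must cover the same nutrients",
         call. = FALSE)
  }
  p0 <- baseline$pct_below
  p1 <- scenario$pct_below
  tibble::tibble(
    nutrient = baseline$nutrient,
    p_baseline = p0,
    p_scenario = p1,
    abs_reduction_pp = p0 - p1,
    rel_reduction_pct = ifelse(!is.na(p0) & p0 > 0, 100 * (p0 - p1) / p0,
                               NA_real_)
  )
}
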