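#' Validate pipeline input tables
#'
#' Schema, referential-integrity and range checks on a recall table and
#' its food-composition table: required columns, food codes resolving,
#' ages within the 5-9 y scope, non-negative grams and compositions.
#'
#' @param recall Recall tibble.
#' @param foods Food-composition tibble.
#' @return Tibble of issues (`severity`, `check`, `detail`); zero rows
#'   means the inputs are clean.
#' @export
validate_inputs <- function(recall, foods) {
  issues <- list(tibble::tibble(severity = character(),
                                check = character(), detail = character()))
  note <- function(severity, check, detail) {
    issues[[length(issues) + 1]] <<-
      tibble::tibble(severity = severity, check = check, detail = detail)
  }
  need_recall <- c("child_id", "age", "sex", "weight", "food_code",
                   "grams", "dairy_subtype")
  miss <- setdiff(need_recall, names(recall))
  if (length(miss) > 0) {
    note("hard", "recall_columns", paste("missing:", paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  miss_f <- setdiff(c("food_code", nutrient_names()), names(foods))
  if (length(miss_f) > 0) {
    note("hard", "foods_columns", paste("missing:", paste(miss_f, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  unknown <- setdiff(unique(recall$food_code), foods$food_code)
  for (code in unknown) {
    note("hard", "food_code", sprintf("unknown food code '%s'", code))
  }
  bad_age <- unique(recall$child_id[recall$age < 5 | recall$age >= 10])
  for (id in bad_age) {
    note("hard", "age_range", sprintf("child '%s' outside 5-9 y scope", id))
  }
  if (any(recall$grams < 0, na.rm = TRUE)) {
    note("hard", "grams", "negative gram amounts in recall")
  }
  if (any(as.matrix(foods[, nutrient_names()]) < 0)) {
    note("hard", "composition", "negative per-100 g composition values")
  }
  bad_sub <- setdiff(stats::na.omit(unique(recall$dairy_subtype)),
                     dairy_subtypes())
  for (s in bad_sub) {
    note("hard", "dairy_subtype", sprintf("unknown dairy subtype '%s'", s))
  }
  dplyr::bind_rows(issues)
}

#' Tabulate dairy consumption by subtype
#'
#' A consumption table in the style of a survey's descriptive dairy
#' table: per subtype (and aggregates for all milk and total dairy),
#' the number and percentage of consumers, mean (SD) and maximum grams
#' per day, and mean (SD) servings per day. Subtype means are among
#' consumers; aggregate rows are population-wide.
#'
#' @param childday Child-day table.
#' @return Tibble, one row per dairy group.
#' @export
dairy_consumption_table <- function(childday) {
  n <- nrow(childday)
  grp <- function(label, grams, population_mean = FALSE) {
    cons <- grams > 0
    base <- if (population_mean) grams else grams[cons]
    tibble::tibble(
      group = label,
      n_consumers = sum(cons),
      pct_consumers = 100 * mean(cons),
      mean_g = if (length(base) > 0) mean(base) else 0,
      sd_g = if (length(base) > 1) stats::sd(base) else 0,
      max_g = if (any(cons)) max(grams) else 0,
      mean_servings = grams_to_servings(
        if (population_mean) mean(grams) else
          if (any(cons)) mean(grams[cons]) else 0)
    )
  }
  milk_g <- rowSums(childday[, paste0("dairy_g_", milk_subtypes())])
  rows <- list(
    grp("total_dairy", childday$dairy_g_total, population_mean = TRUE),
    grp("all_milk", milk_g, population_mean = TRUE)
  )
  for (s in dairy_subtypes()) {
    rows[[length(rows) + 1]] <- grp(s, childday[[paste0("dairy_g_", s)]])
  }
  dplyr::bind_rows(rows)
}

#' Run the full diet-modeling pipeline
#'
#' Orchestrates: intake computation, energy-outlier exclusion, baseline
#' usual-intake adjustment and adequacy, the substitution scenario
#' (fortified for current milk among eligible milk consumers), the
#' tiered addition scenarios (buffalo and fortified, with the chosen
#' cap), scenario comparisons, and the variance-ratio sensitivity
#' sweep. All numbers in the bundle are re-derivable from the returned
#' intermediate tables.
#'
#' @param recall,foods Input tables (see [validate_inputs()]).
#' @param refs Reference table; defaults to the packaged one.
#' @param milks Milk composition table; defaults to the packaged one.
#' @param config Usual-intake configuration.
#' @param addition_cap Per-child cap on added servings (2 main, 1
#'   capped variant).
#' @param sweep_ratios Variance ratios for the sensitivity sweep;
#'   `NULL` skips the sweep.
#' @param sweep_nutrients Nutrients swept (default calcium, vitamin C).
#' @param scenarios Character subset of `c("substitution",
#'   "addition_buffalo", "addition_fortified")`; empty gives a
#'   baseline-only bundle.
#' @param outdir Optional directory: writes the bundle as CSVs.
#' @return List: `childday`, `n_excluded`, `dairy_table`, `baseline`
#'   summary, per-scenario summaries and comparisons, `sensitivity`,
#'   and a `manifest` (config hash, counts).
#' @export
run_pipeline <- function(recall, foods,
                         refs = load_references(),
                         milks = load_milks(),
                         config = usual_intake_config(),
                         addition_cap = 2,
                         sweep_ratios = NULL,
                         sweep_nutrients = c("calcium", "vitamin_c"),
                         scenarios = c("substitution", "addition_buffalo",
                                       "addition_fortified"),
                         outdir = NULL) {
  issues <- validate_inputs(recall, foods)
  if (nrow(issues) > 0 && any(issues$severity == "hard")) {
    stop(paste("input validation failed:",
               paste(issues$detail, collapse = "; ")), call. = FALSE)
  }
  cd <- compute_intakes(recall, foods)
  cd <- flag_energy_outliers(cd)
  kept <- exclude_energy_outliers(cd)
  n_excluded <- attr(kept, "n_excluded")

  usual <- adjust_usual_intakes(kept, config)
  baseline_all <- adequacy_summary(usual, refs, "baseline")
  dairy_table <- dairy_consumption_table(kept)

  bundle <- list(childday = kept, usual = usual, n_excluded = n_excluded,
                 dairy_table = dairy_table, baseline = baseline_all,
                 scenarios = list(), comparisons = list())

  run_one <- function(spec, name, base_pop) {
    res <- run_scenario(base_pop, spec, milks)
    scen_usual <- adjust_usual_intakes(res$eligible, config)
    base_usual <- adjust_usual_intakes(
      base_pop[base_pop$child_id %in% res$eligible$child_id, ], config)
    base_sum <- adequacy_summary(base_usual, refs,
                                 paste0(name, "_baseline"))
    scen_sum <- adequacy_summary(scen_usual, refs, name)
    list(n_eligible = nrow(res$eligible), summary = scen_sum,
         baseline_summary = base_sum,
         comparison = compare_scenarios(base_sum, scen_sum))
  }

  if ("substitution" %in% scenarios) {
    bundle$scenarios$substitution <-
      run_one(scenario_spec("substitution", "fortified"), "substitution", kept)
  }
  for (mk in c("buffalo", "fortified")) {
    nm <- paste0("addition_", mk)
    if (nm %in% scenarios) {
      bundle$scenarios[[nm]] <-
        run_one(scenario_spec("addition", mk, addition_cap), nm, kept)
    }
  }

  if (!is.null(sweep_ratios)) {
    bundle$sensitivity <- sensitivity_sweep(kept, refs, sweep_nutrients,
                                            sweep_ratios)
  }

  bundle$manifest <- list(
    config_hash = rlang::hash(list(config = unclass(config),
                                   addition_cap = addition_cap,
                                   scenarios = scenarios,
                                   n_children = nrow(cd))),
    n_input = nrow(cd), n_excluded = n_excluded, n_final = nrow(kept)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(kept, file.path(outdir, "childday.csv"))
    readr::write_csv(dairy_table, file.path(outdir, "dairy_table.csv"))
    readr::write_csv(baseline_all, file.path(outdir, "adequacy_baseline.csv"))
    for (nm in names(bundle$scenarios)) {
      readr::write_csv(bundle$scenarios[[nm]]$summary,
                       file.path(outdir, paste0("adequacy_", nm, ".csv")))
      readr::write_csv(bundle$scenarios[[nm]]$comparison,
                       file.path(outdir, paste0("reductions_", nm, ".csv")))
    }
    if (!is.null(bundle$sensitivity)) {
      readr::write_csv(bundle$sensitivity, file.path(outdir, "sensitivity.csv"))
    }
  }
  bundle
}

#' Round a summary table the way survey reports print
#'
#' Intakes to integers (or one decimal below 10), prevalences to whole
#' percent, servings to one decimal.
#'
#' @param summary Tibble from [adequacy_summary()].
#' @return Rounded copy.
#' @export
round_for_report <- function(summary) {
  out <- summary
  out$mean <- ifelse(abs(out$mean) < 10, round(out$mean, 1), round(out$mean))
  out$se <- round(out$se, 2)
  out$pct_below <- round(out$pct_below)
  out$pct_above <- round(out$pct_above)
  out
}
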