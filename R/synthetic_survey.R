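#' Specification of a synthetic dietary survey population
#'
#' Describes the population a synthetic 24-h recall survey is drawn
#' from. Defaults emulate the structure of a large school-aged-children
#' survey: ~5800 children aged 5-9 y, per-nutrient log-normal usual
#' intakes whose arithmetic means and SDs match the survey's printed
#' baseline intake table, a within- to between-person variance ratio of
#' 0.73 on the log scale, and a dairy pattern in which ~90% of children
#' consume some dairy but the mean amount is well under one 250 g
#' serving.
#'
#' @param n_children Number of children.
#' @param age_probs Probabilities of ages 5,6,7,8,9 (sums to 1).
#' @param p_female Probability a child is female.
#' @param p_dairy Overall probability a child consumes any dairy on the
#'   recall day (consumer fraction is matched by construction).
#' @param dairy_pattern Tibble with columns `subtype` (see
#'   [dairy_subtypes()]), `p_consume` (marginal consumption
#'   probability), `mean_g`, `sd_g` (gamma-distributed grams among
#'   consumers of the subtype).
#' @param intake_params Tibble with columns `nutrient`, `mean`, `sd`:
#'   arithmetic mean and SD of single-day intake per nutrient.
#' @param variance_ratio Within- to between-person variance ratio r on
#'   the log scale; single-day observations are usual intake times
#'   `exp(N(-sw2/2, sw2))` noise with `sw2 = r * sb2`, so observed
#'   means are unbiased for usual means.
#' @param tea_milk_share Fraction of buffalo/cow milk grams emitted as a
#'   separate tea-with-milk component item (tagged milk; totals are
#'   unchanged).
#' @param seed Integer random seed; identical spec + seed gives an
#'   identical dataset.
#' @return A list with class `population_spec`.
#' @export
population_spec <- function(n_children = 5842,
                            age_probs = rep(0.2, 5),
                            p_female = 0.5,
                            p_dairy = 0.895,
                            dairy_pattern = default_dairy_pattern(),
                            intake_params = default_intake_params(),
                            variance_ratio = 0.73,
                            tea_milk_share = 0.5,
                            seed = 1L) {
  stopifnot(length(age_probs) == 5, abs(sum(age_probs) - 1) < 1e-8)
  if (n_children < 1) stop("n_children must be positive", call. = FALSE)
  if (p_dairy < 0 || p_dairy > 1 || p_female < 0 || p_female > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (variance_ratio < 0) stop("variance_ratio must be >= 0", call. = FALSE)
  if (any(dairy_pattern$p_consume < 0 | dairy_pattern$p_consume > 1)) {
    stop("dairy p_consume must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_children = as.integer(n_children), age_probs = age_probs,
                 p_female = p_female, p_dairy = p_dairy,
                 dairy_pattern = dairy_pattern,
                 intake_params = intake_params,
                 variance_ratio = variance_ratio,
                 tea_milk_share = tea_milk_share, seed = as.integer(seed)),
            class = "population_spec")
}

#' @rdname population_spec
#' @details `default_dairy_pattern()` gives the marginal subtype
#'   consumption probabilities and among-consumer gram distributions of
#'   the emulated survey (buffalo milk 58% at 135 g, cow 23% at 140 g,
#'   goat 3% at 93 g, fortified 1.5% at 206 g, yogurt 17%, ice cream 4%,
#'   dairy dessert 2%, milkshake 1.5%).
#' @export
default_dairy_pattern <- function() {
  tibble::tribble(
    ~subtype,         ~p_consume, ~mean_g, ~sd_g,
    "milk_buffalo",   0.58,       135,     120,
    "milk_cow",       0.23,       140,     108,
    "milk_goat",      0.03,       93,      39,
    "milk_fortified", 0.015,      206,     215,
    "yogurt",         0.169,      157,     180,
    "ice_cream",      0.037,      68,      80,
    "dairy_dessert",  0.020,      140,     120,
    "milkshake",      0.015,      220,     160
  )
}

#' @rdname population_spec
#' @details `default_intake_params()` sets single-day arithmetic means
#'   and SDs per nutrient to the emulated survey's baseline intake table
#'   (SD recovered from the printed standard errors at n = 4861; where
#'   an SE rounds to 0.0 a CV of 0.4 is assumed).
#' @export
default_intake_params <- function() {
  tibble::tribble(
    ~nutrient,      ~mean,  ~sd,
    "energy",       1283,   474,
    "protein",      31.8,   13.9,
    "carbohydrate", 181,    48.8,
    "fat",          50,     27.9,
    "sfa",          20,     13.9,
    "mufa",         13.9,   11.2,
    "pufa",         7.1,    7.0,
    "calcium",      371,    265,
    "phosphorus",   649,    244,
    "iron",         6.6,    7.0,
    "zinc",         4.8,    1.9,
    "vitamin_a",    222,    328,
    "vitamin_d",    1.0,    0.4,
    "vitamin_c",    43,     153,
    "thiamin",      0.8,    0.32,
    "riboflavin",   0.98,   0.39,
    "niacin",       10.0,   7.0,
    "vitamin_b6",   1.0,    0.4,
    "folate",       137,    105
  )
}

# map a dairy subtype tag to its food code
subtype_food_code <- function(subtype) toupper(subtype)

# per-100 g compositions of non-milk dairy foods and the mixed staple
# (synthetic values from standard food-composition sources)
default_other_foods <- function() {
  tibble::tribble(
    ~food_code, ~energy, ~protein, ~carbohydrate, ~fat, ~sfa, ~mufa, ~pufa,
    ~calcium, ~phosphorus, ~iron, ~zinc, ~vitamin_a, ~vitamin_d, ~vitamin_c,
    ~thiamin, ~riboflavin, ~niacin, ~vitamin_b6, ~folate,
    ~retinol_fraction, ~folic_acid_fraction,
    "YOGURT", 61, 3.5, 4.7, 3.3, 2.1, 0.9, 0.1,
    121, 95, 0.05, 0.59, 27, 0.1, 0.5,
    0.029, 0.142, 0.075, 0.032, 7, 1.0, 0.0,
    "ICE_CREAM", 207, 3.5, 24, 11, 6.8, 3.0, 0.5,
    128, 105, 0.09, 0.69, 118, 0.2, 0.6,
    0.041, 0.24, 0.116, 0.048, 5, 1.0, 0.0,
    "DAIRY_DESSERT", 140, 3.5, 21, 4.5, 2.8, 1.2, 0.3,
    110, 90, 0.3, 0.5, 40, 0.05, 0.5,
    0.04, 0.13, 0.3, 0.04, 6, 1.0, 0.0,
    "MILKSHAKE", 112, 3.0, 18, 3.0, 1.9, 0.8, 0.2,
    100, 80, 0.1, 0.35, 40, 0.1, 1.0,
    0.04, 0.15, 0.15, 0.04, 5, 1.0, 0.0,
    "STAPLE", 120, 3.2, 18, 3.6, 1.0, 1.4, 1.0,
    15, 60, 0.9, 0.5, 10, 0.0, 2.0,
    0.08, 0.05, 1.0, 0.08, 12, 0.1, 0.0
  )
}

# milks table -> food-composition rows keyed by MILK_* codes
milk_food_rows <- function(milks) {
  out <- milks
  out$food_code <- subtype_food_code(paste0("milk_", out$milk))
  out$milk <- NULL
  dplyr::relocate(out, "food_code")
}

#' Generate a synthetic 24-h recall survey
#'
#' Draws one recall day per child. Per nutrient, a latent usual intake
#' is log-normal with between-person log-variance `sb2 =
#' log(1 + CV^2) / (1 + r)`; the single observed day multiplies it by
#' `exp(N(-sw2/2, sw2))` noise with `sw2 = r * sb2`, so the observed
#' day has the spec's arithmetic mean and SD while the latent usual
#' intakes are the recoverable ground truth. Dairy items are drawn from
#' the dairy pattern and valued with the milk compositions; the
#' remainder of each child's day is carried by a per-child residual
#' food whose per-100 g composition is defined so that item sums
#' reproduce the child's daily total exactly.
#'
#' @param spec A [population_spec()].
#' @param milks Milk composition table from [load_milks()].
#' @return List with `recall` (one row per child x item), `foods`
#'   (per-100 g compositions for every food code used), `truth`
#'   (per-child latent usual intakes) and `children`.
#' @export
generate_survey <- function(spec, milks = load_milks()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_children
  set.seed(spec$seed)
  nut <- nutrient_names()

  children <- tibble::tibble(
    child_id = sprintf("C%05d", seq_len(n)),
    age = sample(5:9, n, replace = TRUE, prob = spec$age_probs),
    sex = ifelse(stats::runif(n) < spec$p_female, "F", "M")
  )
  children$weight <- round(pmax(
    stats::rnorm(n, mean = 16 + 2.5 * (children$age - 5), sd = 2.5), 10), 1)

  r <- spec$variance_ratio
  usual <- matrix(NA_real_, n, length(nut), dimnames = list(NULL, nut))
  observed <- usual
  for (k in seq_len(nrow(spec$intake_params))) {
    p <- spec$intake_params[k, ]
    cv <- p$sd / p$mean
    s2o <- log(1 + cv^2)
    sb2 <- s2o / (1 + r)
    sw2 <- r * sb2
    mu <- log(p$mean) - sb2 / 2
    u <- stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sb2))
    noise <- exp(stats::rnorm(n, mean = -sw2 / 2, sd = sqrt(sw2)))
    usual[, p$nutrient] <- u
    observed[, p$nutrient] <- u * noise
  }

  # dairy pattern: overall consumer status first (so the consumer
  # fraction matches p_dairy by construction), then subtypes with
  # probabilities scaled conditionally; a designated consumer drawing
  # no subtype falls back to the most common one (buffalo milk)
  pat <- spec$dairy_pattern
  is_consumer <- stats::runif(n) < spec$p_dairy
  grams <- matrix(0, n, nrow(pat), dimnames = list(NULL, pat$subtype))
  if (spec$p_dairy > 0) {
    p_cond <- pmin(pat$p_consume / spec$p_dairy, 1)
    for (j in seq_len(nrow(pat))) {
      takes <- is_consumer & stats::runif(n) < p_cond[j]
      m <- pat$mean_g[j]; v <- pat$sd_g[j]^2
      shape <- m^2 / v
      g <- stats::rgamma(n, shape = shape, rate = shape / m)
      grams[takes, j] <- pmax(g[takes], 1)
    }
    none <- is_consumer & rowSums(grams) == 0
    if (any(none)) {
      m <- pat$mean_g[1]; v <- pat$sd_g[1]^2
      shape <- m^2 / v
      grams[none, 1] <- pmax(stats::rgamma(sum(none), shape = shape,
                                           rate = shape / m), 1)[seq_len(sum(none))]
    }
  }

  milkrows <- milk_food_rows(milks)
  other <- default_other_foods()
  dairy_foods <- dplyr::bind_rows(milkrows, other[other$food_code != "STAPLE", ])
  comp <- as.matrix(dairy_foods[match(subtype_food_code(pat$subtype),
                                      dairy_foods$food_code), nut])
  dairy_contrib <- (grams / 100) %*% comp
  colnames(dairy_contrib) <- nut

  # scale each child's dairy so its contribution never exceeds the
  # drawn day total in any nutrient: item sums then reproduce the
  # latent total exactly, and dairy amounts co-vary with calcium-rich
  # days as in real data
  ratio <- ifelse(dairy_contrib > 0, observed / dairy_contrib, Inf)
  f <- pmin(1, apply(ratio, 1, min))
  grams <- grams * f
  dairy_contrib <- dairy_contrib * f

  # per-child residual food carries the rest of the day's intake
  residual <- pmax(observed - dairy_contrib, 0)
  res_grams <- 300
  res_comp <- residual / (res_grams / 100)
  res_foods <- tibble::as_tibble(res_comp)
  res_foods$food_code <- paste0("RES_", children$child_id)
  res_foods$retinol_fraction <- 0.1
  res_foods$folic_acid_fraction <- 0
  foods <- dplyr::bind_rows(dairy_foods, dplyr::relocate(res_foods, "food_code"))

  # assemble recall rows: dairy items (+ tea-milk split) and residual
  dairy_long <- tibble::as_tibble(grams)
  dairy_long <- dplyr::bind_cols(children["child_id"], dairy_long)
  dairy_long <- tidyr::pivot_longer(dairy_long, -"child_id",
                                    names_to = "dairy_subtype",
                                    values_to = "grams")
  dairy_long <- dairy_long[dairy_long$grams > 0, ]
  dairy_long$food_code <- subtype_food_code(dairy_long$dairy_subtype)
  dairy_long$is_tea_milk <- FALSE
  # split part of buffalo/cow milk into an explicit tea-milk component
  if (spec$tea_milk_share > 0) {
    splittable <- dairy_long$dairy_subtype %in% c("milk_buffalo", "milk_cow")
    tea <- dairy_long[splittable, ]
    tea$grams <- tea$grams * spec$tea_milk_share
    tea$is_tea_milk <- TRUE
    dairy_long$grams[splittable] <-
      dairy_long$grams[splittable] * (1 - spec$tea_milk_share)
    dairy_long <- dplyr::bind_rows(dairy_long, tea)
  }
  res_rows <- tibble::tibble(child_id = children$child_id,
                             dairy_subtype = NA_character_,
                             grams = res_grams,
                             food_code = paste0("RES_", children$child_id),
                             is_tea_milk = FALSE)
  recall <- dplyr::bind_rows(dairy_long, res_rows)
  recall <- dplyr::left_join(recall, children, by = "child_id")
  recall <- dplyr::arrange(recall, .data$child_id, .data$food_code)
  recall <- recall[, c("child_id", "age", "sex", "weight",
                       "food_code", "grams", "dairy_subtype", "is_tea_milk")]

  truth <- dplyr::bind_cols(children["child_id"], tibble::as_tibble(usual))
  list(recall = recall, foods = foods, truth = truth, children = children)
}

#' A ten-child hand-checkable fixture
#'
#' Deterministic tiny dataset covering every addition tier (<0.5,
#' 0.5-0.9, 1-1.4, 1.5-1.9, >=2 servings), a fortified-milk consumer, a
#' dairy non-consumer, a tea-with-milk consumer, an ice-cream-only
#' consumer, and one constructed energy outlier (a staple intake far
#' above the others). All compositions come from the packaged synthetic
#' tables, so every total can be recomputed by hand.
#'
#' @param milks Milk composition table.
#' @return List with `recall` and `foods` tibbles.
#' @export
make_toy_fixture <- function(milks = load_milks()) {
  foods <- dplyr::bind_rows(milk_food_rows(milks), default_other_foods())
  row <- function(id, age, sex, wt, code, g, sub = NA_character_, tea = FALSE) {
    tibble::tibble(child_id = id, age = age, sex = sex, weight = wt,
                   food_code = code, grams = g, dairy_subtype = sub,
                   is_tea_milk = tea)
  }
  recall <- dplyr::bind_rows(
    row("T01", 6, "F", 18, "MILK_BUFFALO", 100, "milk_buffalo"),
    row("T01", 6, "F", 18, "STAPLE", 800),
    row("T02", 6, "M", 19, "MILK_COW", 150, "milk_cow"),
    row("T02", 6, "M", 19, "YOGURT", 30, "yogurt"),
    row("T02", 6, "M", 19, "STAPLE", 750),
    row("T03", 7, "F", 21, "MILK_BUFFALO", 300, "milk_buffalo"),
    row("T03", 7, "F", 21, "STAPLE", 700),
    row("T04", 7, "M", 22, "MILK_BUFFALO", 425, "milk_buffalo"),
    row("T04", 7, "M", 22, "STAPLE", 650),
    row("T05", 8, "F", 24, "MILK_COW", 550, "milk_cow"),
    row("T05", 8, "F", 24, "STAPLE", 700),
    row("T06", 8, "M", 25, "MILK_FORTIFIED", 200, "milk_fortified"),
    row("T06", 8, "M", 25, "STAPLE", 820),
    row("T07", 9, "F", 27, "STAPLE", 900),
    row("T08", 6, "M", 19, "STAPLE", 5000),
    row("T09", 9, "M", 28, "MILK_BUFFALO", 250, "milk_buffalo", tea = TRUE),
    row("T09", 9, "M", 28, "STAPLE", 880),
    row("T10", 5, "F", 16, "ICE_CREAM", 50, "ice_cream"),
    row("T10", 5, "F", 16, "STAPLE", 640)
  )
  list(recall = recall, foods = foods)
}
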