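---
title: "Methods: modeling milk substitution and addition in children's diets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling milk substitution and addition in children's diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairymod)
```

## The problem

School-aged children in low- and middle-income settings frequently fall
short of requirements for calcium, iron, zinc, vitamin A, vitamin D and
several B vitamins. Milk is a widely consumed, culturally established
vehicle for closing part of that gap — either as locally common buffalo
milk or as a fortified (filled) milk beverage carrying added iron,
vitamins A, C and D. `dairymod` implements a diet-modeling pipeline that
quantifies, from a single 24-h dietary recall per child, how much two
counterfactual interventions could reduce the population prevalence of
inadequate nutrient intake:

1. **Substitution** — replace all currently consumed non-fortified milk
   (buffalo, cow, goat, including the milk component of tea) volume by
   volume with fortified milk, among milk consumers who do not already
   consume fortified milk.
2. **Tiered addition** — top children consuming fewer than 2 dairy
   servings/d up to the recommendation of 2–3 servings/d (1 serving =
   250 g), with either buffalo or fortified milk; a capped variant adds
   at most 1 serving/d.

Both are best-case scenarios: full compliance and no compensation
elsewhere in the diet.

## From recall items to child-days

Each recall row is one consumed food (grams, food code, optional dairy
subtype tag). `compute_intakes()` sums `grams/100 ×` the per-100 g
composition into one vector per child covering energy and 18 nutrients,
and accumulates dairy grams by subtype. Two derived columns travel with
the totals: *preformed retinol* and *folic acid*, obtained by
multiplying each food's vitamin A (µg RAE) and folate (µg DFE) by its
`retinol_fraction` and `folic_acid_fraction`. They matter only for the
tolerable upper levels, which apply to preformed retinol and synthetic
folic acid rather than to the total equivalents.

Energy outliers are excluded before any analysis: a child more than
3 SD from the mean energy intake of its 1-y age stratum is dropped, in
a single pass (the rule is not re-applied after exclusion). A technical
note: with a sample SD, no point in a stratum of n ≤ 10 can exceed
3 SD (the maximum standardized deviation is (n−1)/√n), so the rule only
has power in realistically sized strata; the packaged 10-child fixture
therefore carries a constructed outlier that is verified against larger
strata.

Dairy servings are `grams / 250`, kept at full precision internally —
tier boundaries in the addition rule are defined on exact servings and
must not be distorted by display rounding. The 250 g serving is defined
for milk by the dietary guidelines; we apply the same denominator to
yogurt, ice cream, desserts and milkshakes, since no separate serving
size is defined for them in the source guidelines.

## Reference values

`references.csv` (shipped, user-overridable) carries EAR, UL, AMDR
bounds, EER, WHO RNIs and conversion factors by nutrient × age band ×
sex. Most nutrients split at ages 5–8 vs 9 y; iron and zinc follow the
WHO bands 5–6 vs 7–9 y. The vitamin A EAR at age 9 is sex-specific
(420 µg F, 445 µg M). The protein EAR is 0.76 g/kg body weight and is
resolved against each child's weight. Zinc has no directly tabulated
EAR here: it is derived at load time as RNI / conversion factor
(9.6/1.2 = 8.0 mg/d for 5–6 y; 11.2/1.2 = 9.3 mg/d for 7–9 y), rounded
to one decimal as reference tables print it. Iron deliberately has no
EAR: its markedly skewed requirement distribution makes the cut-point
method biased, so iron uses the full probability method (below) on the
RNI at 5% bioavailability (12.6 and 17.8 mg/d). SFA, MUFA and PUFA have
no reference values, and energy carries only the FAO moderate-activity
EER by age and sex (a lookup convenience; no adequacy is computed for
energy).

Milk compositions ship in `milks_synthetic.yaml`. These are **synthetic
defaults** assembled from standard food-composition sources (USDA-style
whole-milk entries; a typical reconstituted fortified filled-milk
powder, which per its product description carries added calcium, iron
and vitamins A, C and D). They are not values from any specific survey
and are meant to be overridden via `load_milks(path)` when local
compositions are available.

## The scenario rules

Substitution moves each non-fortified milk subtype's grams to
fortified milk; the nutrient delta is `g/100 × (fortified − subtype)`
per subtype, dairy grams are exactly preserved, and the tea-milk
component is replaced along with plain milk (all tagged milk grams are
replaced — the sensitivity of results to excluding tea milk can be
probed by re-tagging those rows).

The tiered addition maps current servings *s* to added servings:
2.0 on [0, 0.5), 1.5 on [0.5, 1.0), 1.0 on [1.0, 1.5), 0.5 on
[1.5, 2.0), 0 at ≥ 2 — the published band labels ("0.5–0.9" etc.) read
as half-open intervals of a one-decimal display. This reading
guarantees every treated child reaches at least 2 servings; enumeration
over a fine grid shows post-scenario servings always land in
[2.0, 2.5). The cap binds after the tier (capped variant:
`min(tier, 1)`). Children already consuming fortified milk are excluded
only from substitution, not from addition.

## Usual intakes from a single recall day

A single day per child mixes between-person variation in usual intake
with day-to-day noise; prevalence estimates computed on raw single days
are badly overdispersed. With one day the within-person share cannot be
estimated internally, so it is removed with an **external variance
ratio** r = within:between variance on the transformed scale (default
0.73, the external estimate adopted for all nutrients; sensitivity
swept over 0.2–0.9).

`shrink_to_usual()` works on `log(x + ε)`, with ε half the smallest
positive observed value per nutrient (zeros are rare for the in-scope
nutrients; a two-part consumption model is out of scope). If the
transformed values have mean m and variance s², the usual intake is

&nbsp;&nbsp;`exp( m + (t − m)/√(1+r) + s²·r / (2(1+r)) ) − ε`

— the deviation rescaling shrinks the spread to the between-person
share (s²/(1+r) estimates the between-person variance), and the
half-variance term preserves the implied mean on the original scale,
exactly for log-normal intakes. A final mean-ratio rescale keeps the
mean-preservation contract (< 1%) under zero inflation or extreme skew,
where the log-normal identity is only approximate. The mapping is
strictly increasing: individuals are never reordered. As r → ∞ the
distribution collapses to the preserved mean, so prevalence below any
cutoff tends to 0 or 100 according to the mean-vs-EAR comparison —
which is exactly the drift the sensitivity sweep exhibits.

## Adequacy estimators

* **EAR cut-point**: percent of children with usual intake below their
  own (age/sex/weight-resolved) EAR.
* **Full probability (iron)**: requirement R is log-normal with its
  97.5th percentile anchored at the RNI (`meanlog = log(RNI) −
  1.96·sdlog`) and log-SD 0.25 by default (configurable; the anchor
  uses the only quantities the reference source prints, and in the
  degenerate sdlog → 0 limit the estimator reduces to the EAR
  cut-point at the anchor). Prevalence is the average of
  `P(R_i > y_i)` over children.
* **AMDR**: macronutrients as %E with general Atwater factors 4/4/9
  kcal/g against total energy, classified on inclusive bounds
  (protein 10–30, carbohydrate 45–65, fat 25–35 %E).
* **UL exceedance**: total intake for most nutrients; preformed retinol
  for vitamin A; folic acid for folate.
* **Comparisons**: absolute reduction in percentage points and relative
  reduction `100(p₀ − p₁)/p₀` (reported NA when p₀ = 0), computed on
  the scenario-eligible subpopulation against its own baseline.

Prevalences are always computed on adjusted (usual) intakes — adjust
first, then classify. The SE of the mean is SD/√n (no survey weights
are modeled).

## The synthetic survey generator

No public microdata accompany the emulated survey, so
`generate_survey()` provides populations with known ground truth.
Per nutrient, usual intake is log-normal; the generator takes target
arithmetic means and SDs of the *single-day* intake (defaults match
the emulated survey's printed baseline means, with SD = SE·√n and a
CV of 0.4 where the printed SE rounds to 0) and splits the log-scale
variance into between- and within-person shares via r: `sb² =
log(1+CV²)/(1+r)`. The observed day is `usual × exp(N(−sw²/2, sw²))`,
so observed means are unbiased for usual means and the generator's
`truth` table is exactly the quantity `shrink_to_usual()` should
recover.

Dairy items are drawn by subtype (probabilities and among-consumer
gamma gram distributions matching the emulated survey's dairy table);
the overall dairy-consumer fraction matches its parameter exactly by
construction, with a buffalo-milk fallback for designated consumers
who draw no subtype — subtype marginals are therefore approximate.
Part of the buffalo/cow milk grams is emitted as an explicit
tea-with-milk component item, so the "milk including tea milk" dairy
definition is unambiguous. Each child's dairy grams are scaled down
where needed so that the dairy contribution never exceeds the child's
drawn day total in any nutrient; the rest of the day is carried by a
per-child residual food whose per-100 g composition closes the gap
exactly. Consequences worth knowing:

* Item sums reproduce each child's latent day total *exactly* (the
  generator works backward from totals) — the conservation invariant
  the tests assert.
* Dairy amounts co-vary with calcium-rich days, as in real data, but
  the upper tail of the servings distribution is thinner than in the
  emulated survey (few children reach ≥ 2 servings), because a large
  milk draw is inconsistent with a low independent calcium draw.
* Nutrients are otherwise correlated only through shared food items
  (no explicit copula), so joint macronutrient %E distributions are
  wider than in real diets. Marginal per-nutrient estimators — the
  scope of this package — are unaffected.

Passing tests on these populations therefore demonstrate estimator
correctness under the stated model, not agreement with any real
survey's headline numbers, which depend on request-only microdata.

## Numerical and design choices

* Tier boundaries and the 2-servings adherence threshold are evaluated
  on exact servings; 2.0 servings is inclusive ("meets").
* The energy-outlier rule uses the sample SD, one pass, per 1-y
  stratum; strata of size < 2 are left unflagged with a warning.
* `ear_from_rni()` rounds to one decimal, matching reference-table
  precision; round-tripping back through the conversion factor is
  exact to 0.05·factor.
* Problem sizes in the test-suite: parameter recovery at n = 5000,
  variance-ratio convergence at n = 20 000, closed-form prevalence
  checks at n = 50 000 draws, Monte-Carlo requirement oracle at 10⁵
  draws per child on 100 children — sizes at which the asserted
  tolerances (5%, 10%, 1 pp, 0.5 pp) have comfortable margins.
* The analysis drivers simulate n = 5842 children, the emulated
  survey's analytic sample size.

## Known limitations

* Milk compositions and the iron requirement log-SD are documented
  substitutes, not survey-verbatim values; headline scenario effects
  (e.g. the exact relative reduction in vitamin C inadequacy) shift
  with them. Directions and relative orderings are robust in the
  sensitivity sweeps.
* One recall day per child: consumer/non-consumer status is
  single-day, and episodically consumed foods are noisy; the external
  ratio is a modeled assumption, not an estimate from these data.
* No survey weights, household clustering, seasonality or
  weekday/weekend structure.
* Vitamin B12 is out of scope (absent from the underlying composition
  tables), as are anthropometry-based analyses and cost comparisons.
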