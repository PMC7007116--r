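---
title: "Modelling dietary iron losses under elevated CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dietary iron losses under elevated CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroclim)
```

## The problem

Crops grown under elevated atmospheric CO2 (~550 ppm, the level projected
for mid-century) carry measurably less iron in their edible portions.
Field trials show declines of roughly 4–10% concentrated in C3 grains
(wheat, rice, barley), legumes, and maize, while sorghum and potato show
no statistically significant change. Because the change is a decline in
nutrient *content* of familiar foods rather than a change in the foods
themselves, consumers are unlikely to perceive or adapt to it. For
populations that already draw most of their iron from affected vegetal
sources — disproportionately the poorest, and the groups most vulnerable
to iron deficiency, children aged 1–5 and women of childbearing age
(15–49) — even modest percentage losses matter.

`ferroclim` implements that exposure model as a reusable pipeline: it
takes per-country per-food edible supply tables, food composition data,
age-sex relative-intake factors, crop effect estimates with uncertainty,
anemia prevalence, and population counts, and produces per-country
distributions of total percentage dietary iron loss, a risk
classification, a vegetarian counterfactual, and a dietary-diversity
statistic. A synthetic-data generator produces complete input bundles
with the statistical structure the method assumes, so the whole pipeline
is testable at desk scale.

## The model, stage by stage

### Age-sex disaggregation

National per-capita supplies (g/person/day) are converted to group
supplies by one of two paths:

* **Relative-intake scaling.** If a food belongs to a dietary-database
  food group with a modelled relative-intake factor for (country, group),
  the group supply is `national × factor`. The worked example: a national
  pumpkin supply of 23.8 g/d and a factor of 0.958 (women of childbearing
  age eat vegetables 4.2% below the national average) give 22.8 g/d.
* **Energy fallback.** Foods with no matching food group are assumed
  eaten in proportion to the group's average dietary energy requirement:
  the factor is `requirement / national calorie supply`. The worked
  example: cassava at 216.8 g/d with an energy factor of +0.9% gives
  218.8 g/d.

The fixture returned by `cameroon_fixture()` encodes the energy factor
as exactly +0.9% (requirement = 2175 × 1.009 kcal/d). The underlying
requirement is usually quoted as 2200 kcal/d, which would give ≈1.15%;
the +0.9% figure is the one the downstream arithmetic (216.8 → 218.8)
actually uses, so the fixture reproduces the printed chain.

Two deliberate simplifications: factors enter here as point values
(their uncertainty is propagated only in the Monte Carlo stage, where it
belongs with the other uncertainty sources), and group diets are not
renormalised to group energy totals after scaling — the method is
defined per food, and renormalising would silently change the published
worked example. A food whose group has no factor row for a particular
country falls back to energy scaling rather than failing, so partial
factor coverage stays usable.

### Iron accounting

Iron per food is `supply × density / 100` (densities are mg per 100 g
edible portion). One density per food is carried; regional
nutrient-table variation is outside the model's scope, and the synthetic
generator controls densities directly. Totals are decomposed into three
source classes for reporting: affected vegetal (C3 grains, legumes,
maize), unaffected/unknown vegetal (zero-effect crops and other vegetal
foods), and animal.

### Effect distributions

Each crop or category effect arrives as a mean percentage change with a
95% uncertainty interval and a sample count. Three rules turn these into
sampling laws:

* **Zero-effect rule.** Entries with p > 0.05 (sorghum, p = 0.153;
  potato, p = 0.555) become a point mass at exactly zero. The 0.05 level
  matches the classification of those two p-values as non-significant.
* **Category pooling.** `pool_category()` forms a category effect as the
  sample-count-weighted average of member crops, with interval bounds
  pooled by the same weights and counts added.
* **Skew-normal fit.** `fit_skew_normal()` finds the (location, scale,
  shape) skew-normal law whose median equals the reported mean and whose
  2.5%/97.5% quantiles equal the reported interval. Treating the three
  numbers as three quantiles is the minimal well-posed reading of
  "derived from the uncertainty intervals": three constraints, three
  parameters.

The fit is solved by separating the parameters: the asymmetry ratio
`(q97.5 − median)/(median − q2.5)` of the standard law depends on the
shape alone and is strictly monotone in it, so a one-dimensional root
search identifies the shape, after which scale and location follow
linearly. Quantiles are evaluated through the exact CDF
`Φ(z) − 2T(z, α)` with Owen's T computed by 64-node Gauss–Legendre
quadrature (reduced to |a| ≤ 1 by the standard identity), and roots are
polished to 1e-12; residuals above 1e-9 raise an error. One consequence
worth knowing: the skew-normal family cannot represent arbitrary
asymmetry. As the shape grows the law approaches the half-normal, whose
asymmetry ratio is ≈2.436 (reciprocal ≈0.4104). A triple outside that
range — for example (−5, −10, −3), ratio 0.4 — admits no skew-normal law
and raises a fit error reporting the residuals. Self-consistency tests
therefore generate their random triples *from* skew-normal laws, which
guarantees feasibility; this is also why the synthetic generator keeps
its interval asymmetry within the representable range.

### Monte Carlo propagation

`simulate_losses()` runs n = 1000 iterations by default. Per iteration:

* one percentage change is drawn per distinct effect entry and shared by
  every food and country mapped to that entry — the effect is a property
  of crop biology, not geography, so a draw represents one "state of the
  world" for that crop;
* one multiplicative intake perturbation is drawn per relative-intake
  factor, log-normal with unit mean and coefficient of variation
  `factor_sd / factor` (factors are positive multipliers, so a
  log-normal law is the natural positive-support choice; the published
  method states that this uncertainty is propagated but not its law);
* the country/group loss is the iron-weighted mean decline, reported as
  a positive percentage: `loss = −Σ(iron_f × Δ_f) / Σ(iron_f)`.

Effect and intake draws are coupled within an iteration (drawn once per
iteration each). Because the weights are nonnegative, every draw's loss
is a convex combination of its per-food losses — a structural bound the
test suite checks draw by draw. Everything is reproducible from a single
seed.

### Risk classification

Per-country median losses are crossed with anemia prevalence:

| loss \\ anemia          | > 20%    | ≤ 20% |
|------------------------|----------|-------|
| > 3.8%                 | HIGH     | MILD* |
| 3.1–3.8% (inclusive)   | MODERATE | MILD  |
| < 3.1%                 | NONE     | NONE  |

The default cutoffs 3.1/3.8 are the published tertile boundaries
(`tertile_mode = "FIXED"`), so published classifications reproduce on
any dataset; `"RECOMPUTE"` derives them as the 1/3 and 2/3 empirical
quantiles of the losses at hand, which is what synthetic worlds use.
The cell marked * is not stated by the published rule (it names HIGH
only above the anemia threshold and sends the lowest tertile to NONE
regardless of anemia); MILD is the conservative reading and the choice
is exposed in `risk_config()`. Boundary conventions: a loss exactly at a
cutoff belongs to the middle band, and anemia exactly at 20% is "not
over" the threshold.

`top_lost_sources()` aggregates, over the HIGH-risk (country, group)
units, each food's per-capita iron × its expected fractional loss ×
headcount, in kg/day. The expected loss is the analytic mean of the
food's fitted effect law, making the table deterministic; both study
groups are summed, the most direct reading of "summed across all
populations" given the model only carries the two study groups.

### Vegetarian counterfactual and dietary diversity

The vegetarian scenario removes all animal-source foods from the
national-average diet and inflates every remaining vegetal food by one
scalar per country, `total energy / vegetal energy`, conserving calories
exactly. The single-scalar reading is the simplest consistent
interpretation of a "proportional increase in the remaining vegetal
foods"; the scenario runs on national-average diets, as the published
analysis does. Loss simulations for baseline and scenario share a seed,
so the per-country increment is a paired difference.

The diversity statistic is the smallest number of foods supplying 99% of
a country's dietary iron (ties broken by food id for determinism); the
99% threshold excludes foods consumed in negligible proportions. It is
regressed on log anemia prevalence by OLS (natural log; the base only
rescales the slope). Whether the published curve is `n ~ log(anemia)` or
`log(n) ~ anemia` is not decidable from the text; the former is the
default and the latter is available via `log_response = TRUE`, with no
claim that either matches the published figure. The wild-harvest
robustness check drops flagged countries: since reliance on unreported
wild foods is not one of the input tables, a country is flagged when
wild-harvest foods carry more than 5% of its national dietary iron — a
proxy that lets the generator plant both flag states.

The income correlate is a plain Pearson correlation between log GDP per
capita (an optional `population.csv` column) and the nonanimal iron
share — reporting only, no model.

## The synthetic generator

`generate_world()` emulates the structure of the real inputs:

* supplies are log-normal (right-skewed) with one staple grain boosted
  to 40% of national calories (`staple_share`), then rescaled so the
  energy audit matches the stated national calorie supply exactly;
* affected-category effects fall in the measured −10% to −3% band;
  sorghum and potato carry the published non-significant p-values;
* relative-intake factors are log-normal around 1 with standard
  deviations in 0.02–0.15;
* anemia prevalences span 5–60% by default, and high-anemia countries
  get a wider supply spread (and fewer animal foods), so iron
  concentrates in fewer foods there — making the negative
  diversity–anemia association recoverable downstream, along with a
  negative income–nonanimal-share correlation;
* each table draws from its own RNG stream derived from the master seed
  by a fixed offset, so regenerating one table never perturbs another,
  and identical configurations give bit-identical bundles.

What it does **not** emulate: real country diet compositions, trade
structure, within-group age gradients (one factor per declared group; the
published worked example quotes a single age inside the 15–49 band, and
whether real factors vary within it is not resolvable), seasonal
variation, or regional nutrient-density differences. Passing tests on
synthetic worlds therefore demonstrate the *mechanics* of the method —
accounting identities, propagation, classification — not empirical claims
about any real country. The published global headline numbers depend on
the real supply/intake/anemia datasets and are out of desk-scale reach;
what the suite checks instead is qualitative structure (non-empty
tertiles, cereal-dominated top-loss tables when cereals dominate iron).

## Numerical choices and degenerate inputs

* Skew-normal CDF: 64-node Gauss–Legendre quadrature for Owen's T
  (error far below the 1e-9 fit tolerance); quantiles by `uniroot` on
  the CDF to 1e-12 within |z| ≤ 10.
* Point-mass laws (zero-effect crops, entries without an interval)
  bypass fitting entirely.
* Zero supply and zero iron are legal inputs everywhere except where a
  share or a loss is genuinely undefined (zero total iron), which raises
  a domain error naming the unit.
* Ties in the diversity ranking break by food id; quantiles use R's
  default (type 7) definition, which also places `{1..9}` into thirds
  at the tertile cutoffs.
* `n_draws = 1` is allowed: summaries collapse onto the single draw.

## Problem sizes

The test suite runs worlds of 3–20 countries with 16–30 foods and
100–1000 draws; the Monte Carlo correctness check uses 100,000 draws on
a five-food diet, and distributional fits are validated on 200 random
triples. These sizes make every structural property checkable in
seconds while leaving the full pipeline identical to what a 152-country
run would execute.

## Worked example

```{r cameroon}
b <- cameroon_fixture()
d <- disaggregate(b$supply, b$foods, b$gdd, b$energy, "women_15_49")
d[c("food_id", "g_per_day", "provenance")]
```

## Known limitations

The model stops at dietary iron *supply*: bioavailability (heme vs
nonheme absorption, phytate and ascorbic acid, iron stores) and iron
status are out of scope, as are diet substitution under changing prices
and incomes, fortification programs, and the construction of real
supply data from food balance sheets. Anemia prevalence is an imperfect
proxy for iron deficiency — it has non-iron etiologies and misses
non-anemic deficiency — and is used only as a broad relative indicator
in the risk cross-classification.
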