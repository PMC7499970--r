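---
title: "Methods: FODMAP composition databases and intake estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FODMAP composition databases and intake estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodmapr)
```

This vignette documents the models, conventions and design choices behind
`fodmapr`: how the composition database represents FODMAP content, how
composite foods are resolved, how intake is accounted and summarised, what
the synthetic survey generator does and does not emulate, and the numerical
decisions a careful user should know about.

## The composition database

A database is a tibble with one row per food item. Every FODMAP-relevant
component — fructose, glucose, fructan, lactose, galacto-oligosaccharides
(GOS) and polyols — is stored as a triple of columns: the amount in grams
per 100 g *fresh (edible) weight*, a provenance label, and a free-text
source label. Glucose is not itself a FODMAP; it is carried solely so the
excess-fructose rule can be evaluated.

**Absent is not zero.** A missing value (`NA`) means "content unknown",
which is distinct from a measured zero. Intake computation treats absent
values as contributing 0 g — the only defensible default when summing a
day — but the distinction is preserved in the database so that coverage can
be audited with `provenance_census()`, and diary summaries carry a
completeness flag wherever a consumed food could not be resolved at all.

**Provenance.** Each stored value is labelled `direct_measurement`,
`dry_weight_converted`, `component_sum`, `similarity_assigned` or
`recipe_derived`. The census counts values of the five FODMAP groups by
group and provenance and reports the direct-measurement share as an
integer percent, rounded half-up (so a share of 74.8% reports as 75, and
38.5 would report as 39 rather than base R's round-half-to-even 38).

**Unit conversion.** Analytical values reported per 100 g dry matter are
converted on load with `dry_to_fresh()`: `fresh = dry × (1 − w)` where `w`
is the food's water mass fraction, taken from the composition table itself
rather than an external lookup. The conversion requires `w < 1`; a food
that is literally all water has no meaningful dry-matter basis.

**Component sums.** Where a total is not analysed directly, the loader
builds it from parts: GOS = raffinose + stachyose, polyols = sorbitol +
mannitol, and total fructan approximated by summing fructo-oligomer
analyses (the kestose/nystose series). Sums are tagged `component_sum`,
and the oligomer sum is additionally marked as an approximation in its
source label, because higher-degree polymers it misses make it a lower
bound.

**Similarity assignment** copies values from an analysed food to an
unanalysed analogue (frozen from fresh vegetables, bulgur from couscous).
It is driven by an explicit two-column mapping table; no fuzzy name
matching is attempted, because that matching is expert judgement, not an
algorithmic step. Assignment fills *absent* slots only — a value already
stored on the target, whatever its provenance, is never overwritten. This
is deliberately stricter than "don't overwrite direct measurements": a
similarity guess should never displace any recorded value, and the rule
makes the census bookkeeping exact (the total grows by exactly the number
of values copied).

**Conflicting sources.** When several rows describe the same food id, the
loader keeps, per component, the value from the highest-precedence row
that reports one (precedence column, default row order, so later rows
win). A source that detected an analyte therefore beats one that did not,
which is the behaviour wanted when one laboratory reports fructan in a
food and another reports none. How to resolve disagreements in *magnitude*
is genuinely open; explicit precedence is our convention, chosen because
it is auditable from the input file alone.

## Composite foods and recipes

`resolve_recipe()` computes a composite's per-100 g value as

```
value = ( Σ_i fraction_i × value_i ) / yield_factor
```

where `fraction_i` are ingredient mass fractions of the raw mix (summing
to at most 1; any remainder is water or FODMAP-free) and `yield_factor` is
the mass of finished food per unit mass of raw mix. The yield factor
defaults to 1 and is our explicit convention: published recipe
calculations rarely state whether composite values are per raw or per
cooked mass, yet flour-to-bread conversion cannot be stated without one,
so the parameter is exposed rather than implied. Recursion through nested
composites is allowed, cycles are an error, and nesting is capped (default
10) to catch pathological recipe graphs.

A component absent from *every* ingredient stays absent in the composite;
absent from only *some* ingredients is treated as 0 there and flagged, so
partially-covered composites remain distinguishable from fully-covered
ones.

`decompose_entry()` is the dual operation on diaries: a recorded portion
of a composite becomes ingredient-level entries of
`amount × fraction_i / yield_factor` grams. Both paths give identical
person-day totals by construction, and the test suite checks this path
independence on randomly generated recipe graphs.

**Fermented breads.** Yeast fermentation degrades fructan, so a
recipe-derived fructan value computed from flour overstates the bread
actually eaten. The package does not model fermentation kinetics; instead
it warns when a recipe-derived profile is created for an item flagged as
fermented bread, steering such foods toward measured or
similarity-assigned values.

## The accounting model

Per person-day:

* `excess fructose = max(0, fructose − glucose)` — fructose is co-absorbed
  with glucose, so only the surplus is counted as malabsorbable;
* `total oligosaccharides = fructan + GOS`;
* `total FODMAP = excess fructose + total oligosaccharides + lactose +
  polyols`.

The excess-fructose floor is applied **at the day level** by default: the
day's fructose and glucose totals are accumulated first and the floor
applied once. An `item_level` mode applies the floor per food and sums.
Day-level is the default because the floor models co-absorption of the
monosaccharides present together in the gut, not per-food-label
arithmetic; since `max(0, ·)` is subadditive under aggregation, the
day-level figure is never larger than the item-level one, and the suite
checks that ordering on random diaries.

All arithmetic is double precision; values are rounded (2 decimals,
integer percents) only at presentation.

## Intake estimation

Per-person intake is the arithmetic mean over the person's recorded days,
each day weighted equally — weekday and season labels are carried for
stratified reporting but do not enter the estimator. The population mean
of each component is the mean of per-person means with a Student-t
confidence interval, `mean ± t(0.975, n−1)·sd/√n`. The t interval was
chosen over a normal interval because survey sizes of interest are
n ≈ 100–120 and per-person means are already day-averaged (and so close to
normal); no within/between-person variance decomposition or usual-intake
deattenuation is attempted — the estimand is the mean of the observed
record period.

Unresolved foods (absent from both the database and the recipes) abort the
pipeline by default, listing the offending ids; a permissive mode skips
them and sets the person-day completeness flag, for exploratory runs.

**Sample size.** `sample_size(z, sd, margin)` inverts the confidence
half-width: `n = ⌈(z·sd/margin)²⌉`. With z = 1.96, an anticipated
between-person SD of 2.5 g/day and a margin of 0.47 g/day this gives 109,
i.e. on the order of 110 persons for a fructan-precision-driven survey.

**Energy screen.** Mis-reporting is screened by comparing mean reported
energy intake (EI) with estimated expenditure `EE = BMR × PAL`. BMR uses
sex- and age-band linear equations (`slope × weight + intercept`, MJ/day)
of the FAO/WHO/UNU style, shipped as a data file
(`inst/extdata/bmr_coefficients.csv`) rather than hard-coded, so national
variants can be substituted; bands cover ages 10–200 with the convention
`age_min ≤ age < age_max`. PAL comes from the persons table, defaulting to
1.6 (a light-activity value) with a logged message when missing. The
screen reports both the ratio of means and the mean of per-person ratios
with its t interval — the two differ in skewed data, so both are exposed —
and flags persons strictly below a configurable cutoff, default 0.76, a
conventional Goldberg-type screening bound. The cutoff is a screen, not a
verdict: a low ratio indicates possible under-reporting, nothing more.

Energy is MJ internally; 1 kcal = 4.184 kJ where conversion is needed.

## Ranking reports

"Most commonly eaten foods containing X" (`rank_sources()`) filters to
foods with stored content of X > 0 and ranks by the population mean grams
of the *food* eaten per day — per-person g/day averaged over **all**
persons, zeros included for non-consumers — so staples outrank
rarely-but-heavily eaten foods. A consumer-only mean is available as a
flag. "Highest content per 100 g" (`top_content()`) ranks stored contents,
with an excess-fructose variant using `max(0, fructose − glucose)` per
100 g that therefore excludes glucose-dominated foods. Ties break
alphabetically by name, making both rankings invariant to diary row order.
Category shares are integer percents, rounded half-up; with many
categories the rounded shares can drift from 100 by up to half the number
of categories, which the reports tolerate rather than hide with remainder
fudging.

## The synthetic survey generator

Because real survey microdata and proprietary composition databases cannot
be redistributed, `fodmapr` ships a generator whose defaults emulate the
structure of a national-survey FODMAP study: 117 persons × 4 diary days; a
category-structured food list (cereals, vegetables/roots/legumes,
fruits/berries, dairy, desserts/snacks, composites, non-carbohydrate
foods); ~12 recorded items per person-day (Poisson); gamma portion sizes
with category-level means (50–250 g); log-normal per-100 g contents with
category-specific presence patterns (fructan in all cereals, lactose only
in dairy, fructose with accompanying glucose in fruit, polyols scattered);
composites defined purely by recipes over base foods; start weekdays and
seasons cycling over persons so all are covered at group level; and
demographics (76% women, ages 18–70, sex-specific weights, PAL ≈ 1.7).

**Calibration.** After drawing contents, one deterministic scale factor
per component rescales the database so the closed-form expected intakes —
`Σ_foods E[items/day] × P(food) × E[portion] × content/100`, composites
resolved through their recipes — exactly equal configurable targets. The
shipped targets are day-mean magnitudes typical of an adult Western diet
(fructose 15.2, glucose 15.5, fructan 3.46, lactose 14.2, GOS 0.43,
polyols 1.31 g/day; energy 8.1 MJ/day), so the end-to-end demo operates on
a realistic scale. `ground_truth()` returns these expectations, which is
what makes parameter-recovery testing possible: the five component means
and energy are linear in the generated quantities and have closed forms;
day-level excess fructose and total FODMAP are non-linear (the `max(0,·)`
floor) and deliberately have none.

**Under-reporting** is modelled as a fraction of persons whose recorded
amounts are all multiplied by a constant (default multiplier 0.7, default
fraction 0); the ground truth scales by the expected factor accordingly.

**What passing tests do and do not show.** The generator's diaries are
exchangeable across days and foods are chosen independently item by item.
Real diaries have day-to-day correlation within persons, meal structure,
seasonal composition variation, correlated food choices, ripeness and
fermentation effects on content, and item-specific under-reporting of
"unhealthy" foods — none of which are modelled, and provenance labels on
synthetic values describe census structure only, not a real measurement
history. Recovery and coverage results on synthetic data therefore
validate the *estimators and plumbing* (unbiasedness under the stated
model, interval construction, path independence), not robustness to those
real-data features.

**Validation problem sizes.** The suite checks: interval coverage of the
ground-truth means over 200 replicated surveys at the default 117 × 4
design (expected ≈95%, accepted 90–99% per component, a binomial band at
200 replicates); confidence-interval width halving from 25 → 100 → 400
persons; ground-truth recovery under full under-reporting at multiplier
0.7; and byte-level determinism of all generated tables given a seed.
Seeds are threaded explicitly through every stochastic call (no reliance
on ambient RNG state).

## Numerical choices and degenerate inputs

* Negative amounts, invalid water fractions and malformed tables are
  errors at the boundary (`validate_db()` reports findings as data; strict
  loaders refuse).
* An empty person-day yields an all-zero vector, not an error; an empty
  database census reports zero counts with an explicit `empty` flag
  instead of a 0/0 share.
* A population summary requires n ≥ 2 (a one-person "CI" would be
  meaningless); zero recorded days is an error.
* Percent rounding is half-up everywhere percentages are printed.
* Recipe fraction sums may fall short of 1 (water/FODMAP-free remainder)
  but exceed 1 only within 1e-8 tolerance.

## Known limitations

* No usual-intake modelling: estimates describe the recorded days, and
  short records overstate between-person variance relative to habitual
  intake.
* No retention/loss factors for individual sugars during cooking, and no
  fermentation chemistry; yield factors capture mass change only.
* The excess-fructose rule is a binary floor on day totals; it does not
  model dose-dependent co-absorption capacity.
* Similarity assignment quality is entirely determined by the supplied
  mapping table; the package checks structure, not nutritional sense.
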