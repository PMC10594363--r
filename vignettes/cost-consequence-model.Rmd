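---
title: "The cost-consequence model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cost-consequence model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costconseq)
```

## The analysis in one paragraph

`costconseq` implements a trial-based cost-consequence analysis of an early
parent-mediated intervention (PACT) for preschool autistic children, added to
treatment as usual (TAU), against TAU alone. Per-child resource use over the
13-month trial window is costed at country-specific 2020 euro prices and
aggregated under three nested perspectives: healthcare service (intervention
delivery, speech and language therapy, community health and social services,
hospital services), broader service (plus education/childcare and social
care), and societal (plus parental productivity losses and informal care).
The headline statistic is the incremental cost — the mean per-child cost in
the intervention arm minus the control arm — per perspective, at 13 months
and, after temporal extrapolation with discounting, at 6 years. A waterfall
decomposition shows how the category-level differences accumulate from the
delivery cost down to the societal total. Uncertainty is quantified by
non-parametric bootstrap; three deterministic sensitivity analyses probe
unit-cost assumptions, long-run family-impact hours, and out-of-pocket
expenses.

## Costing model

Per-child category cost is the sum over the category's items of quantity
times unit price. Two categories are hour-denominated and use dedicated
valuations:

* **Parental productivity** (human-capital approach): hours off work ×
  national average wage (`wage_per_hour`, €/h).
* **Parental informal care** (market-price / proxy-good approach): unpaid
  care hours × the hourly price of an equivalent formal caregiver
  (`informal_care_price_per_hour`, €/h).

All computation is in euros at 2020 prices; `inflate_to_2020()` applies a
configurable multiplicative index for inputs at an earlier price level (or
converted from another currency — the conversion factor folds into the same
multiplier, since no separate exchange-rate treatment is needed for a purely
multiplicative adjustment).

Items with a pooled mean occurrence of at most 0.5 events per child over the
13-month window are excluded before costing (`filter_items()`, threshold
configurable). This mirrors the simplification used when unit costs must be
found in several countries: very rare items are not worth pricing. Note that
with the default fixtures this filter genuinely bites — the rare inpatient
stay item falls below 0.5 pooled events and is dropped from microdata runs.

## Perspectives and incremental costs

Perspectives are plain sets of categories (`perspective_spec()`), so the
incremental cost under a perspective is the sum of its per-category mean
differences. Three structural properties follow and are enforced by tests:
additivity over nested perspectives, antisymmetry under arm exchange, and
homogeneity of degree one in prices. The waterfall is the same information
presented cumulatively; its default order runs delivery → health services →
education and social care → family impacts, and its final bar equals the
societal incremental exactly (same summands, same order of addition).

Out-of-pocket expenses are deliberately outside every default perspective;
they enter only the third sensitivity analysis.

## Temporal extrapolation to 6 years

Long-term resource-use data are unavailable, so 13-month costs are projected
with fixed yearly estimates (`schedule_rules()`):

* **Annualization.** A 13-month cost becomes a yearly rate via
  `annualization_factor`, default 12/13 (the window is treated as 13 months
  of steady use). Setting the factor to 1 treats trial-window costs as
  already yearly; both readings are defensible because the original
  conversion is not documented, and the factor is exposed rather than fixed.
* **Delivery** is limited to year 1, which covers the 13-month delivery
  window; the roughly one-month overhang into year 2 is ignored rather than
  prorated. The full 13-month delivery cost (not an annualized rate) is
  booked in year 1, so nothing of it is lost.
* **Education/childcare** runs at the nursery-derived yearly cost during
  years 1–2 and is recosted as primary-school time from year 3 onward. The
  school-time yearly cost is a per-arm configuration input
  (`school_cost_map`); the packaged fixtures set it equal across arms on the
  assumption that all children attend the same standard school provision.
* **Every other category** repeats its annualized yearly cost each year.

Discounting uses 1/(1+r)^t at r = 3.5% per year. The convention is
configurable because published totals cannot disambiguate it: the default
(`start_undiscounted`) leaves year 1 undiscounted, the usual practice in
health-technology appraisal; `end_of_year` discounts every year once. The
6-year total for a flat 100 €/yr stream under the default convention is the
geometric series 100·(1 − 1.035⁻⁶)/(1 − 1.035⁻¹) ≈ 551.51 €, which the test
suite checks to 1e-9 relative error against the term-by-term sum.

## The synthetic cohort generator

No per-child microdata are public, so the generator (`generate_cohort()`)
emulates them: 74 intervention and 69 control children; one quantity per
child per item; zero-inflated gamma quantities (zero with probability
`zero_prob`, otherwise gamma with the configured conditional mean and shape
`dispersion`). Shape defaults to 1 (exponential), the usual stand-in for
strongly right-skewed cost data; the packaged nursery-attendance item uses
shape 4, since attendance is more regular than episodic service contacts.
Intervention delivery is a *fixed* item: quantity exactly 1 per intervention
child and 0 per control child, reflecting a once-per-child programme cost.
A single integer seed drives two independent per-arm streams, so resizing
one arm never perturbs the other arm's draws.

`calibrate_to_means()` rescales item mean quantities so the *expected*
per-child cost per (arm, category) hits a target exactly, allocating within
multi-item categories proportionally to prior expected costs (equally among
cost-carrying items if all priors are zero). The England fixture is
calibrated to the published 13-month arm totals — 7,651 vs 1,723 € under the
healthcare service perspective, 95,689 vs 99,308 € societal, delivery
difference 6,198 € — with the category split inside each perspective chosen
as plausible synthetic values (the published component table is not
reproduced here). Ireland, Italy and Spain fixtures are scaled variants and
are purely illustrative, as are all packaged unit-cost values.

What the generator does **not** emulate: correlation between items within a
child (no covariance information exists to calibrate it), covariate
structure (age, severity), or longitudinal within-child persistence.
Passing calibration-recovery tests therefore shows that the generator and
costing chain are mutually consistent, not that the synthetic cohorts are
distributionally faithful to the trial families.

## Deterministic and stochastic model modes

The published analysis is an aggregate-mean simulation model, not a
microdata re-analysis. The pipeline mirrors that: when driven by a
calibration-target table, headline tables, incrementals, waterfalls and
projections are computed from the calibrated *expected* arm summaries
(`expected_arm_summaries()`), which reproduce the published totals exactly
and deterministically; the synthetic per-child cohort generated from the
same configuration feeds only the bootstrap. This matters quantitatively:
with informal-care means near 70,000 € per child and exponential-scale
skew, the standard error of a 143-child societal difference is an order of
magnitude larger than the −3,619 € point value (the trial itself reported
the difference as non-significant), so a single simulated cohort cannot be
expected to carry the sign. When the pipeline is instead given a per-child
cohort CSV, everything is computed from that microdata.

## Uncertainty

`bootstrap_incremental()` resamples children with replacement within each
arm independently (the child is the unit of independence), recomputes the
incremental per replicate, and reports the percentile interval; 1,000
replicates by default, 95% level. The point estimate is always the
statistic on the original data, so it is invariant to seed and replicate
count. Percentile intervals were preferred to BCa for transparency; with
cost data this skewed, an interval that is asymmetric around the point
estimate is expected behaviour, not an error.

## Sensitivity analyses

1. **Unit-cost scaling** (`apply_unit_cost_scale()`): unit costs of chosen
   categories scaled by 1 + δ, δ ∈ {±20%, ±30%, ±50%} in the default grid
   (`sa1_grid()`); everything downstream is recomputed. Because costs are
   linear in prices, scaling all societal categories by λ scales every
   incremental by exactly λ — a property used as a correctness check.
   When education is scaled, the school-time recosting scales with it, so
   the homogeneity identity holds across the full 6-year horizon.
2. **Family-hours taper** (`apply_hours_taper()`): productivity-loss and
   informal-care hours reduced by 20% from year 3 onward (school age),
   years 1–2 unchanged. The taper is applied to the cohort-mean yearly
   stream, not to child-level ages, since the model is mean-based.
3. **Out-of-pocket comparison** (`compare_out_of_pocket()`): the trial
   intervention arm's mean out-of-pocket spend against an external Irish
   observational estimate for usual care (living costs, care and
   assistance, education, healthcare, travel, training/support, autism
   assistance dog; 2020 prices). The two cohorts come from different
   studies; no statistical harmonization beyond price inflation is
   attempted, matching the source comparison's own design. With the
   published means 1,696 vs 9,599 € the difference is −7,903 € and the
   contrast (9,599 − 1,696)/9,599 ≈ 82.3%.

Scenarios are pure transforms: they act on a copy of the model, and the
base model re-evaluates bit-identically afterwards.

## Numerical and degenerate-input choices

* Zero-magnitude scenarios (δ = 0, taper 0) are exact identities, bit for
  bit.
* A category absent from an arm summary is treated as 0 with a warning (not
  an error), so partial analyses remain possible.
* A waterfall order may omit categories only when their difference is
  exactly zero; it must begin with the delivery category.
* Calibration to a zero target zeroes the category; a positive target on a
  category whose items cannot carry cost (all prices zero or certain zero
  use) is an error.
* Bootstrap CIs require at least 2 children per arm and at least 100
  replicates; below that the point estimate is still returned with the CI
  flagged absent.
* Monetary values are rounded to whole euros only in the human-readable CSV
  tables (totals are sums of the rounded rows, so tables stay internally
  additive); the JSON manifest keeps full precision.

## Problem sizes used by the test suite

The suite favours sizes that make Monte-Carlo checks sharp but cheap: the
law-of-large-numbers check uses 10,000 children per arm; calibration
recovery uses 25,000 per arm (50,000 children total); the bootstrap
enumeration oracle uses a 2+2-child toy with 10,000 replicates against the
16-path exhaustive distribution; pipeline determinism runs the full bundle
twice at 150 bootstrap replicates. The whole suite completes in well under
a minute.

## Known limitations

* The 6-year projection inherits everything the fixed-yearly-cost
  assumption ignores: no cost trajectories, no differential attrition, no
  outcome-dependent resource use.
* Category-level splits inside the published perspective totals, all unit
  costs, and the non-England fixtures are synthetic; the package reproduces
  the published perspective-level arithmetic exactly, but its 6-year totals
  are those of its own schedule and discounting choices, not the published
  ones (whose annualization and discount conventions are not documented).
* Clinical and behavioural outcomes are reported alongside costs in a
  cost-consequence framing and are out of scope here; no
  cost-effectiveness ratios or QALYs are computed.
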