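# costconseq

Cost-consequence analysis of early interventions for autistic children,
with temporal extrapolation, bootstrap uncertainty and deterministic
sensitivity analyses.

## What this package is for

Parent-mediated early interventions such as PACT (a 12-session
video-feedback programme delivered on top of treatment as usual, TAU) are
clinically effective, but a within-trial economic evaluation sees only the
first 13 months — when the delivery cost dominates. `costconseq` is for
health economists and modellers who want to re-run and stress-test the
longer-horizon arithmetic: cost per-child resource use at country-specific
2020 euro prices, aggregate under nested analytic perspectives, project the
13-month picture over 6 years with explicit schedule rules and discounting,
and quantify how the conclusion moves under uncertainty and assumption
changes.

## The model

For arm $a$ and cost category $c$, the per-child mean cost is

$$\bar{C}_{a,c} = \frac{1}{n_a}\sum_{i \in a}\sum_{j \in c} q_{ij}\, p_j,$$

with quantities $q_{ij}$ (events or hours over the 13-month window) and
unit prices $p_j$. Parental time off work is valued at the national average
wage (human-capital approach); informal care hours at the market price of a
formal caregiver. Items with pooled mean occurrence $\le 0.5$ events per
child are excluded before costing. The incremental cost under perspective
$P$ (a set of categories) is

$$\Delta_P = \sum_{c \in P}\left(\bar{C}_{\mathrm{int},c} - \bar{C}_{\mathrm{ctl},c}\right),$$

for the healthcare-service, broader-service and societal perspectives at
13 months and, after projection, at 6 years. Projection applies fixed
yearly costs: delivery in year 1 only, nursery costs in years 1–2 recosted
as school time from year 3, all other categories annualized (× 12/13 by
default) and repeated, each year discounted by $1/(1+r)^{t-1}$ at
$r = 3.5\%$. Uncertainty comes from a child-level non-parametric bootstrap
within arms; sensitivity analyses scale unit costs (±20/30/50%), taper
family-impact hours by 20% from year 3, and compare out-of-pocket expenses
against external observational data.

Because no trial microdata are public, the package ships a synthetic cohort
generator (zero-inflated gamma quantities, 74 + 69 children) with a
calibration mode that reproduces target arm-level category costs exactly in
expectation. The packaged England fixture is calibrated to the published
perspective-level arm totals; the within-perspective splits, all unit-cost
values and the other country fixtures are synthetic illustrations (files
are named accordingly).

## Worked example

```r
library(costconseq)

model <- example_model("england")   # calibrated, deterministic (expected means)
ev <- evaluate_model(model)
ev$incrementals
#>   perspective        horizon   difference
#> 1 healthcare_service 13 months   5928.
#> 2 healthcare_service 6 years     4823.
#> 3 broader_service    13 months   4510.
#> 4 broader_service    6 years     1536.
#> 5 societal           13 months  -3619.
#> 6 societal           6 years   -39848.
```

At 13 months the intervention costs the health service 5,928 € more per
child (7,651 vs 1,723 €), but society as a whole 3,619 € *less* (95,689 vs
99,308 €), driven by lower informal-care hours. Over 6 years the societal
saving deepens to about −39,800 € per child while service costs stay
higher — the delivery investment is repaid many times over once family
impacts are counted. The waterfall shows the accumulation:

```r
ev$waterfall_13m
#>   category                difference cumulative
#> 1 pact_delivery                 6198       6198
#> 2 speech_language_therapy       -180       6018
#> 3 community_health_social        -70       5948
#> 4 hospital_health                -20       5928
#> 5 education_childcare          -1200       4728
#> 6 social_care                   -218       4510
#> 7 parental_productivity        -1000       3510
#> 8 parental_informal_care       -7129      -3619
```

The out-of-pocket sensitivity analysis (Irish usual-care data vs the trial
intervention arm):

```r
fx <- example_fixture("ireland")
compare_out_of_pocket(
  out_of_pocket_comparison(fx$oop$pact_mean, breakdown = fx$oop$breakdown)
)
#> $difference
#> [1] -7903
#> $contrast_pct
#> [1] 82.33149
```

A full report bundle (cost tables, incrementals, waterfalls, schedule, SA
grid, bootstrap, JSON manifest) for any packaged country:

```r
cfg <- example_run_config("england", out_dir = "run1", seed = 1)
run_pipeline(cfg)
```

or from the shell via the thin CLI:

```sh
Rscript inst/cli/costconseq.R report --country england --seed 1 --out run1/
```

See `vignettes/cost-consequence-model.Rmd` for the full account of the
model, its assumptions and the design choices.

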