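---
title: "An anthropometric food demand model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anthropometric food demand model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrisim)
```

## The model in one pass

`nutrisim` projects national food demand from the body outwards. The
chain evaluated at every 5-year timestep (1965–2100) per country is:

1. **Diet quality → young-adult height.** `H(15–19) = α_s G^β_s`, with
   `G` the mean of animal-source plus empty calories over the three
   preceding timesteps — roughly the growing period of the cohort.
   Adult cohorts keep their height as they age (one age class per step;
   the open 100+ class absorbs). Child heights are the growth-standard
   reference at the cohort midpoint age, scaled by the factor by which
   the 15–19 cohort diverges from the standard's 18-year height.
2. **BMI-class shares.** The population of each broad age group
   (0–14, 15–59, 60+) and sex is distributed over BMI classes by
   saturating income curves (below).
3. **Body weight.** `W = B (H/100)²` per class, with representative
   BMIs `B` = 17.5/19.25/22.5/27.5/32.5/37.5 kg/m² for the six adult
   classes and, for the five child z-score bands, the growth-standard
   median BMI shifted by the representative z-score.
4. **Intake.** Schofield BMR (`γW + δ`, weight-based 1985 coefficients)
   times a physical activity level `A = p·1.53 + (1−p)·1.76`, where the
   inactivity share `p` rises with income. Aggregation over classes,
   cohorts and sexes is population- and share-weighted, plus a
   pregnancy/lactation add-on `N · P(0–4)/5` per capita.
5. **Waste and demand.** `D/I = ε Y/(ζ+Y) + 1`; waste `X = D − I`.
6. **Composition.** Nested tree: animal `L = ηY/(θ+Y)·D`, then empty
   `E = ιY/(κ+Y)·(D−L)`, then fruit/veg/nut `V = λY/(μ+Y)·(D−L−E)`,
   staples as remainder. The nesting guarantees the groups sum to total
   demand exactly, for any parameters and income.

The only exogenous drivers are income (USD2005 PPP/cap/yr) and
population by cohort and sex; everything else is endogenous, with no
time-dependent parameters.

## Functional form of the BMI-share curves

Each class share follows `s_b(Y) = c_b + d_b·Y/(k_b + Y)` (`d_b` may be
negative for classes that shrink with income), clipped to [0, 1] and
renormalized across classes. This is the simplest form that gives a
finite saturation prevalence of overweight and obesity at very high
incomes, which is also the model's main conservatism: if prevalence in
rich countries keeps drifting upward beyond the income trend, the model
underestimates it.

The *default* parameter set additionally imposes, within each
(age group, sex) stratum, a shared half-saturation income with
`Σ c_b = 1` and `Σ d_b = 0`. Under these constraints the raw curves
already form a proper distribution at every income, so clipping and
renormalization are inactive and the shares a fitted model predicts are
exactly the curves it fitted. This matters for validation: it makes
simulate-and-refit an identity on noiseless data, which the test suite
exploits. Fitting itself never assumes the constraint — each class curve
is estimated independently.

## Tunable parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `α_s`, `β_s` | height scale / elasticity | cm, – | 115/108, 0.060/0.055 (m/f) |
| `c, d, k` per class | BMI share base, saturation delta, half-saturation | –, –, USD | see `default_parameters()$bmi` |
| PAL curve | inactivity base/delta/half-saturation per age group | –, –, USD | children flat; working 0.10–0.14 + ~0.3; retired 0.25–0.28 + 0.35 |
| sedentary, active | PAL multipliers | – | 1.53, 1.76 (category midpoints of the standard classification) |
| `ε`, `ζ` | waste asymptote, half-saturation | –, USD | 0.45, 10 000 |
| `η/θ, ι/κ, λ/μ` | diet-tree asymptote / half-saturation | –, USD | 0.45/8000, 0.35/6000, 0.25/4000 |
| `N` | pregnancy + lactation add-on per newborn-year | kcal/day | 460 |
| `child_bmi_sd_frac` | one child z-score SD as fraction of median BMI | – | 0.10 |

The pregnancy add-on is a convention (roughly 300 kcal/day of pregnancy
plus 500 kcal/day of lactation averaged over a year and discounted for
coverage); it is configurable and its aggregate effect is small
(≈ 5–10 kcal/cap/day). The Schofield coefficients ship as a data file
(`inst/extdata/schofield_coefficients.csv`) in kcal/day, converted from
the published MJ/day table at 4.184 kJ/kcal; the height-inclusive and
temperature-dependent BMR variants are deliberately out of scope, the
coefficient table being replaceable through the `coeffs`/`schofield`
arguments.

The bundled growth standard is a *stylized synthetic* table
(`growth_standard_synthetic.csv`) shaped like the official child/
adolescent references; users with access to the official tables can
supply them in the same CSV schema.

## Fitting

All saturating curves are estimated by Levenberg–Marquardt nonlinear
least squares with multi-start initialization of the half-saturation at
{0.1, 1, 10} × median income; the best residual sum of squares wins,
ties going to the smallest half-saturation. The height power law is
ordinary least squares in log–log space. Observations are equally
weighted; population weighting would be a defensible alternative and is
left to the user by pre-aggregating panels. Intake is not directly
observable, so the waste curve is fitted to the ratio of *observed*
demand to the model's own intake reconstruction (fitted anthropometric
parameters driven by the observed diet-quality panel) — the same
two-stage structure a practitioner faces with availability data.

Flat responses are handled explicitly: the half-saturation constant of a
constant curve is unidentifiable and is returned as `NA` with a note,
rather than as an arbitrary number.

## Calibration

Calibration is additive: factor = reported − modeled at a calibration
year, per country (and stratum, for heights and BMI shares). Factors are
applied to every timestep of a projection; calibrated values are cut off
below zero, shares are cut off above one and renormalized, and demand is
floored at intake (waste cannot be negative). Every cut is recorded in
the scenario's `clip_log`. At the calibration year every non-clipped
calibrated cell reproduces its reported value exactly. One
simplification relative to a full historical recalibration: a single
calibration year is used rather than year-specific factors over the
whole historical period, which keeps the factor a single well-defined
object per variable.

## Counterfactuals and decomposition

Counterfactual switches re-evaluate one timestep: BMI mass is moved into
the normal class (adults 20–25 kg/m², children −1…1 SD — the natural
destination, being the class whose requirements define a "healthy"
reference), the inactive fraction is given the active multiplier, or
demand is set equal to intake. Composition is re-split from the changed
demand rather than held fixed, since the tree depends only on income and
total demand. The zero-waste change is algebraically `−100·X/D`.

Demand growth between two timesteps is decomposed by chained
(sequential-substitution) substitution in the fixed order population →
requirements (demographic structure + height) → BMI → activity → waste →
composition. Chaining makes the contributions sum *exactly* to the net
change; the price is order dependence, which is surfaced rather than
hidden: the reversed order is always computed and the spread reported,
and a Shapley average over all 6! orders is available via
`shapley = TRUE` (cheap, because the evaluation is memoized over the
2⁶ factor subsets).

## The synthetic world generator

`make_drivers()` produces logistic income paths between country-specific
floors (400–3000 USD) and ceilings (20 000–80 000 USD) — wide enough to
identify every half-saturation constant, which is exactly what real
cross-country panels provide and narrow-income panels do not — and a
cohort-component population with Gompertz-like survival and a fertility
proxy declining with income, so pyramids age as countries grow rich.
`make_observations()` runs the forward model with known parameters and
perturbs the outputs: multiplicative log-normal noise on calorie
quantities (default SD 0.02) and heights (0.005), additive Gaussian
noise on share logits (0.05), with shares renormalized and the observed
demand panel defined as the sum of the perturbed composition groups so
panels stay internally consistent. The noise scales are conventions in
the range of national reporting accuracy, not an estimate of any real
residual structure.

What the generator deliberately does **not** emulate: measurement error
correlated across years or variables, reporting gaps, income shocks or
reversals, migration, conflict mortality, or any real country's
statistics. Passing the recovery and cross-validation tests therefore
shows the estimation machinery is correct and well-identified under the
model's own assumptions — it does not validate the model against the
real world, which requires reported height/BMI/availability panels.

## Numerical choices

* The diet-quality driver `G` is the model's own lagged animal + empty
  calories (in the four-group tree, oils sit in empty calories and
  pulses in staples, so `L + E` is the closest observable aggregate).
  At the model start, where no lagged history exists, the first
  timestep is solved by fixed-point iteration of the
  height→intake→composition loop (relative tolerance 1e−13; it
  contracts fast because height enters with exponent `2β ≈ 0.12`), and
  the fallback is logged. With an observed `G` panel the current-year
  value is used instead.
* Initial adult heights are set to the first young-adult value per sex;
  calibration overrides them where reported data exist.
* Cohorts map to Schofield brackets by midpoint age (e.g. 15–19 →
  bracket 10–18).
* Shares are clipped then renormalized; ties in the multi-start fit go
  to the smallest half-saturation; all stochastic steps (world
  generation, noise, fold assignment) are seeded and the simulator
  itself is deterministic — repeated runs are bit-identical.
* Energy is kcal/cap/day internally; joules (1 kcal = 4184 J) appear
  only in reporting aggregates (`global_aggregate()`, EJ/yr).

## Problem sizes in the test suite

The packaged tests run the full pipeline on 30-country, 28-timestep
worlds (the scale at which all half-saturation constants are comfortably
identified), use 50 replicate noisy panels for the bias check, and one
million randomized evaluations for the conservation identities. A full
30-country run takes well under a second; a complete fit about half a
second.

## Known limitations

* A single aggregate driver (income) carries all socio-economic
  variation; urbanization, prices, education and inequality are
  implicit. Saturating shares mean overweight prevalence at very high
  incomes is conservatively capped near the curve asymptotes.
* The animal-calorie share never declines at high income; diets that
  turn away from animal-source foods are outside the default model.
* Calibration offsets are frozen, so calibrated projections inherit the
  base-year discrepancy indefinitely.
* The decomposition's factor bundles (e.g. structure + height as
  "requirements") are a modelling choice; alternative bundles change
  attribution, which is why the order spread and Shapley variant are
  exposed.
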