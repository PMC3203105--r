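---
title: "Methods: a proportional multi-state life table for obesity pharmacotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a proportional multi-state life table for obesity pharmacotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmslt)
```

## Overview

`pmslt` evaluates one-year pharmacological weight-loss interventions
(sibutramine 10 mg daily, orlistat 120 mg three times daily) offered to
obese adults, against a no-intervention comparator, from a health-sector
perspective with a lifetime horizon.  Two populations are simulated in
parallel life tables: a reference population at current morbidity and
mortality, and an intervention population identical except for the
drug-induced BMI shift.  The difference in discounted
disability-adjusted person-years is the health gain; intervention costs
net of disease-cost offsets divided by that gain is the incremental
cost-effectiveness ratio (ICER).

The population is split into sex × 5-year cohorts (baseline ages 20–24
through 95–99, simulated from the band midpoint), each followed in
annual cycles until extinct or age 100.  Nine diseases causally linked
to BMI are modelled explicitly; everything else enters through baseline
all-cause mortality and a baseline years-lived-with-disability (YLD)
rate.

## Exposure: weight change and its BMI translation

The mean loss at the end of the 12-month course is an intent-to-treat
trial estimate (4.45 kg, SE 0.426, sibutramine; 2.89 kg, SE 0.316,
orlistat) and is therefore applied to all starters without further
adjustment for non-adherence.  Weight is held at the 12-month value
through the intervention year and regained from the following month.

Two published regain rates exist for the maintenance phase: a
trial-observed 0.385 kg/month and a meta-regression estimate of 0.0309
(SD 0.0084) kg/month.  They differ forty-fold and cannot both describe
the same trajectory; only 0.385 kg/month is consistent with the
observation that all lost weight is typically regained within two years
(4.45/0.385 ≈ 11.6 months of regain), so 0.385 is the package default
and 0.0309 remains available as the `"meta_regression"` preset.  No SD
is published for the 0.385 rate; the PSA scales the printed 0.0084
proportionally (0.0084 × 0.385/0.0309 ≈ 0.105 kg/month), a package
choice.

Because weight changes continuously while the model cycles annually,
each cycle uses the retained loss at the cycle midpoint (month
12y − 6) as its representative exposure; the midpoint minimises the
within-cycle bias of either endpoint.  `mean_loss_at_year()` reports the
end-of-year value used in scenario definitions (year 1 = the 12-month
loss; the 23%-permanent scenario retains 0.23 × L indefinitely; the
linear-3-year mode interpolates the non-permanent part to zero over 36
months).

Kilogram losses convert to BMI units via fixed mean heights of 1.78 m
(men) and 1.64 m (women) — configurable, since the conversion heights
are not part of the published parameter set.  Per sex × age stratum the
baseline BMI is normal; the counterfactual is the mixture in which the
treated fraction (uptake × obese mass) of the BMI ≥ 30 segment is
translated down by L/height².

## Risk: log-linear RRs and the potential impact fraction

Relative risks per +1 kg/m² compound multiplicatively, RR(x) =
r^(x − x_ref), with r by disease and age band and the reference fixed at
the theoretical-minimum mean of 21.  The incidence change is the
potential impact fraction

PIF = (E_base[RR] − E_cf[RR]) / E_base[RR],

which is provably independent of the reference (it cancels in the
ratio); the package asserts this property in its tests.  Risk below age
35 is treated as unrelated to BMI for all nine diseases — this is why
the 20–29 age group gains nothing from a transient exposure change — and
the clamp age is configurable via `default_rr_table(min_rr_age = ...)`.

Numerically, the public `mean_rr()`/`pif()` functions use adaptive
quadrature over a 10-sigma window of the density, split at the mixture's
kink points (BMI 30 and 30 − shift) so every panel is smooth.  The
pipeline's inner loop instead uses a fixed two-panel Gauss–Legendre grid
(120 nodes per panel, split at BMI 30 so the obese-tail indicator never
cuts a panel), which vectorises over all strata and Monte Carlo RR draws
at once.  For a normal baseline the counterfactual expectation
decomposes as E_cf = E_base − u(1 − r^(−δ))·T(r), where T is the
obese-tail partial expectation, so each draw needs only two matrix
products.  Both routes are tested against each other, against the
lognormal closed forms, and against 10⁶-sample Monte Carlo.

## Disease models

Each disease follows three states (well, diseased, dead-from-disease)
in annual difference equations.  All flows are applied simultaneously to
start-of-cycle stocks:

p′ = p + (1 − p)·i·(1 − PIF) − p·(r + f)

with disease deaths p·f handed to the life table.  A sequential
operator ordering would make the steady state depend on the order
(e.g. incidence-then-fatality converges to i(1−f)/(f + i(1−f)) rather
than i/(i+f)); the simultaneous convention is adopted because it
reproduces the canonical steady-state prevalence i/(i+f) exactly and
makes the annual model the literal Euler step of the continuous
three-state model.  Remission is fixed at 0 for all nine diseases
(chronic-disease convention; cancers are instead costed per incident
case).

Baseline cohort prevalence is generated by the model itself under a
steady-state assumption: the synthetic-cohort prevalence curve obtained
by running each disease from age 20 with current rates.
`derive_obese_baseline()` implements the corresponding derivation of
prevalence among the obese: the whole population is counterfactually
given the renormalised BMI ≥ 30 distribution, the implied
obese-to-population incidence ratio E_obese[RR]/E_pop[RR] scales the
incidence rates, and the disease model is run over the youngest cohort's
lifetime.

## Life table and DALYs

Survivorship declines as l(a+1) = l(a)·exp(−m(a)); person-years use the
half-cycle correction L(a) = (l(a) + l(a+1))/2; the terminal boundary at
age 100 is identical in both arms.  Intervention total mortality
subtracts the summed disease-mortality deltas (clamped at zero with a
logged count, though the clamp never binds under the default world);
disability adjusts the baseline YLD rate additively by Σ Δp_d·w_d,
clamped to [0,1].  Additive prevalence-delta disability (rather than a
multiplicative comorbidity adjustment) is the standard proportional
formulation and reproduces the null case exactly.  DALYs averted are the
cohort-size-weighted, discounted (3%/yr, referenced to the intervention
year) sum of ΔL_w.  Burden fractions compare the intervention gain with
the gain under the ideal scenario in which every stratum has BMI
N(21, 1) permanently.

## Costs

Intervention costs comprise the subsidised annual drug price (A$1,467
sibutramine, A$1,486 orlistat; no uncertainty distribution, as the price
is centrally determined), 10 minutes of GP time at A$109.36/h for the
initial prescription, and 1.3/1.6 follow-up visits at the A$30.20
consultation fee.  Attrition (48%/33%, half in the first month, half at
six months) enters twice, deliberately on two different metrics: the
reported year-equivalent of drug use counts early dropouts as zero
(giving the published 0.64/0.75), while costing charges them one month
of drug cost (completers 12, late dropouts 6 months).  Patient time
(A$17.44/h covering consultation, 30 minutes waiting and 30 minutes
travel) and travel (A$7.45/trip) are reported as a separate perspective.

Cost offsets credit averted incident cases (cancers) or averted
prevalent case-years (chronic diseases) at age/sex-specific 2003 AUD
costs; because the intervention also extends life, later prevalent cases
among the extra survivors partially offset the savings, and the
`all_other` per-person costs of those added person-years form the third,
widest perspective.  All three net-cost perspectives and their ICERs are
always reported; the sensitivity grid quotes the widest one.

## Uncertainty and sensitivity analysis

The PSA (default 2000 iterations) draws the mean weight change
(normal), ln RR per schedule entry (normal, SD from the printed 95%
CIs), the regain rate (normal), and the three triangular minute
components; draws are common to both arms within an iteration.  The
reference arm contains no drawn parameter and is computed once per run;
the baseline-prevalence derivation likewise uses point-estimate RRs and
is held fixed across draws.  The ICER point estimate is the ratio of
means; its uncertainty interval comes from the percentiles of the
per-iteration ratio, and the probability of cost-effectiveness is the
fraction of draws below the A$50,000/DALY threshold.
`uncertainty_spec()` exposes scale factors on every spread, so a fully
degenerate PSA collapses onto the deterministic estimate (a property the
tests assert).

The univariate grid reruns the deterministic model for: halved regain,
linear 3-year regain, 23% permanent loss, a 0.017 utility per
BMI-unit-year added to the effect side, 0% discounting, all obese
disease-free at baseline, and age-decade subgroups 20–79.

## The synthetic world

Because the original demographic and epidemiological inputs are not
published in full, the package generates an internally consistent
stand-in so that every stage runs and every test is reproducible:

* **Mortality** is Gompertz per sex at band midpoints (α = 1.35×10⁻⁴,
  β = 0.081 men; α = 4.0×10⁻⁵, β = 0.092 women), chosen to span ~10⁻³ to
  ~0.3 deaths/person-year between ages 20 and 97 as adult all-cause
  mortality does.
* **Population counts** start at 650,000 per sex in the 20–24 band and
  decline exponentially above age 52, giving ≈14.4 million adults.
* **Disease incidence** rises log-linearly with age from
  disease-specific onset ages at rates and levels set to plausible
  chronic-disease magnitudes (e.g. IHD 0.008/person-year in men at 60),
  with flat case fatality, zero remission, zero male incidence for the
  female-only cancers, and a small seeded lognormal jitter (CV 3%)
  across strata.
* **BMI** is normal per sex with SD 4.5 (men) / 5.0 (women); the mean is
  solved in closed form so P(BMI ≥ 30) matches the 21%/23% obesity
  prevalence targets exactly.
* **Baseline YLD** is a constant 0.10 at every age; only its deltas
  matter for incremental results.
* No secular BMI trend is applied (steady-state baseline); a per-year
  mean-drift hook exists in `generator_config()`.

The generator reproduces the *shape* of the real inputs — exponential
mortality, age-increasing incidence, realistic obesity prevalence and
cost magnitudes — but is not calibrated to actual Australian data, so
absolute DALY and ICER levels differ from published Australian figures
even though every internal relationship (steady states, PIF algebra,
attrition arithmetic, scenario orderings) is exact.  Passing tests
therefore demonstrate correctness of the machinery and of the
directional structure of results, not agreement with any national
estimate.

## Problem sizes and numerical conventions

Default runs simulate 2 sexes × 16 cohorts × 9 diseases over 80 annual
cycles; a deterministic run takes well under a second and the
2000-iteration PSA about half a minute per drug.  Tie-breaks and
degenerate inputs: ICERs with non-positive DALYs report an infinity
sentinel (printed `∞`); mortality after delta subtraction clamps at 0
with a logged count; prevalence clamps to [0,1]; triangular samplers
degenerate to the mode when the spread is zero; reported ICERs round to
two significant figures while all internal arithmetic is full precision.

## Limitations

Drug side-effects, productivity effects, secular obesity trends,
risk-dependent case fatality and comorbidity interactions are out of
scope.  The proportional linkage assumes small prevalence deltas;
uptake-linearity of DALYs (tested at the 5% level) degrades for
near-total exposure shifts, which is why the ideal-scenario burden is
computed with the same machinery rather than by extrapolation.
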