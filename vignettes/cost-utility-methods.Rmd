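---
title: "Methods: trial-based and model-based cost-utility analysis of gallstone management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based and model-based cost-utility analysis of gallstone management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholecea)
```

## The decision problem

Uncomplicated symptomatic gallstones can be managed by laparoscopic
cholecystectomy (LC) or conservatively (CM: analgesia and lifestyle
advice), with surgery still available later if symptoms demand it.
`cholecea` evaluates the two strategies from the UK NHS perspective
(GBP, 2019–2020 price year) in two complementary ways:

1. a **within-trial cost–utility analysis** over 24 months of follow-up
   in a two-arm randomised trial, and
2. a **Markov cohort model** extrapolating to a 10-year horizon with
   monthly cycles.

All incremental quantities use the **CM minus LC** orientation: a
negative incremental cost means CM saves money, a negative incremental
QALY means CM loses health. In the south-west quadrant of the
cost-effectiveness plane the ICER is a saving per QALY forgone, so the
quadrant label is always reported with the ratio.

Because participant-level trial data of this kind are not publicly
available, the package ships a **synthetic-trial generator** whose
defaults emulate the emulated trial's observable margins. Every stage
of the pipeline is therefore testable end-to-end, including
parameter-recovery simulations against closed-form ground truth.

## The synthetic trial generator

`trial_params()` fixes the study conditions; the defaults are the
margins of the emulated trial:

* 217 participants per arm across 20 centres (uniform assignment);
* age ~ Normal(50.5, 11) years (the s.d. is an assumption; only the
  mean is reported for the emulated trial), 71% women;
* cumulative cholecystectomy uptake by month 24 of 70.5% (LC) and
  29.5% (CM);
* theatre time ~ Gamma with mean(s.d.) 72(42) min (LC) and 83(49) min
  (CM); hospital stay ~ Gamma with 0.63(1.3) and 1.4(3.4) days;
* readmission probabilities 9.7% and 12.9%; A&E attendance rates
  0.221 and 0.469 per participant (the reported A&E counts divided by
  the number of responders per arm);
* primary-care visits ~ Poisson with mean 6 per participant over the
  24 months (an assumption: roughly one consultation per quarter for a
  symptomatic condition), with a mean-one log-normal centre effect
  (`centre_sd = 0.2`) standing in for between-centre cost variation.

**Utility trajectories.** Utilities are SF-6D-style values on
$[-0.59, 1]$. Each participant's latent trajectory is
piecewise-constant: baseline $b_i$ (truncated Normal(0.70, 0.12),
typical of symptomatic gallstone cohorts) until surgery; a transient
post-operative dip of depth 0.10 for 2 months; then a steady state
$b_i + 0.03$ (the `surgery_benefit`), with an optional LC-minus-CM
shift (`arm_utility_effect`, default 0). Visit-level noise is
Gaussian (s.d. 0.10) truncated to the instrument range. The visit
schedule defaults to 0, 3, 6, 12, 18, 24 months; the emulated trial
does not state its schedule, so this is a design choice. Months to
surgery follow a Gamma distribution truncated at 24 months (shape 1.5;
scale 4 for LC, 8 for CM), reflecting right-skewed NHS waiting times
and later conversion in the conservative arm.

**Missingness.** `apply_missingness()` masks post-baseline utility
visits only (baseline is a covariate and is never masked). Under MAR
the masking probability is logistic in the observed baseline utility
(coefficient $-2$: sicker participants respond less) and arm
($+0.3$ for CM); the intercept is found by root-finding so the
realised expected rate equals the target (default 20%, configurable —
the emulated trial does not report its questionnaire response
pattern).

**Ground truth.** `truth_summary()` computes the per-arm expected
discounted cost and QALY in closed form. QALY expectations use the
linearity of the trapezoidal rule: the expected AUC equals the AUC of
the expected visit utilities, which integrate the truncated-normal
noise mean over the baseline distribution by one-dimensional
quadrature. Cost expectations combine uptake, the truncated-gamma
probability that surgery falls in year 1 versus year 2, and the
resource-use means.

What the generator does **not** emulate: within-participant serial
correlation beyond the shared baseline level, clinical complications
as distinct events, informative (MNAR) nonresponse, COVID-era
disruption of surgical scheduling, and centre effects on anything but
primary-care intensity. Passing recovery tests therefore show that
the estimators are unbiased *under this data-generating process*, not
that they are robust to every feature of real trial data.

## Outcomes: QALYs and costs

`auc_qaly()` integrates the utility trajectory by the trapezium rule
(standard practice in trial-based economic evaluation) and discounts
each trapezoid by the factor of the year containing its midpoint.
Discounting follows the "no discounting within year one" convention:
the factor is $1$ for year 1 and $(1+r)^{-(y-1)}$ for year $y > 1$,
with $r = 3.5\%$ per year by default. Missing utilities are an error
at this layer — imputation happens upstream, deliberately, so that
uncertainty from imputation propagates through the analysis rather
than being hidden in the outcome calculation.

`participant_cost()` prices resource use with a six-item unit-cost
table (surgical episode, theatre minute, bed-day, readmission
episode, A&E attendance, primary-care visit). Surgical components are
discounted at the year containing `surgery_month`; recurring items
carry the mean of the yearly factors, i.e. they are apportioned
evenly across follow-up years (a design choice — their timing is not
recorded). The bundled `unit_costs_synthetic` table is illustrative
and clearly labelled as such: the emulated trial costed from NHS
reference costs whose exact values are not published, so absolute
cost levels here cannot be validated against it, only the analysis
machinery.

## Within-trial analysis

`adjusted_incrementals()` regresses per-participant total cost and
QALY on the arm indicator plus the trial's minimisation factors
(centre as fixed effects — 20 centres justify fixed rather than
random effects — age, sex) and baseline utility. The QALY model is
linear. The cost model is also an identity-link GLM, with an HC1
heteroscedasticity-robust standard error to respect the skewed,
bimodal cost distribution (operated versus unoperated participants).
This was a genuinely open design point: gamma models with log link
are a common choice for cost regressions, but their covariate-
adjusted *marginal* arm contrast (recycled predictions) is not
consistent when the true cost surface is additive in the covariates,
as it is for resource-count-driven costs, and the gamma likelihood is
undefined for the zero-cost participants that arise when nobody
operates and no care is consumed. The identity-link arm coefficient
is the incremental cost in GBP directly, stays unbiased under
additive cost generation — which the parameter-recovery simulations
in the test suite verify — and handles zeros; distributional
non-normality is absorbed by the bootstrap, which supplies all
interval estimates. Centres with a single participant are pooled into
the largest centre with a warning.

`impute_missing()` is chained-equations multiple imputation with
Bayesian linear-regression draws: for each visit column, coefficients
and residual variance are drawn from their posterior given observed
rows, and missing cells are filled with posterior-predictive noise
(proper imputation), clamped to the instrument range. Predictors are
arm, centre, age, sex, baseline utility and the other visit columns.
Five sweeps per imputation suffice here because the missingness
pattern is non-monotone but low-dimensional. Point estimates pool
`m = 20` imputations by Rubin's rules.

Joint uncertainty uses **bootstrap-then-impute**: resample
participants with replacement stratified by arm, perform a single
stochastic imputation within each resample, refit, and keep the joint
$(\Delta C, \Delta Q)$ pair. This preserves the correlation between
cost and effect differences and propagates imputation noise into the
intervals; `B = 1000` by default, with percentile intervals. The CEAC
at threshold $\lambda$ is the fraction of draws with positive
incremental net benefit $\lambda \Delta Q - \Delta C$ (ties count
one half); the INB is reported at £13 000, £20 000 and £30 000 per
QALY, bracketing the usual UK decision threshold.

## The Markov model

States: *NoSurgery* (symptomatic, untreated), a *Recovery* tunnel
entered at surgery, then *SymptomsResolved* or *SymptomsPersist*, and
absorbing *Death* reachable from every state via life-table
mortality. The cohort (start age 50.5 years, 71% women, sex-weighted
mortality) enters in *NoSurgery* and runs 120 monthly cycles.

Key choices:

* **Surgery hazards.** Months 1–24 take an empirical monthly schedule;
  the default is the constant hazard whose cumulative uptake matches
  70.5% (LC) / 29.5% (CM). Beyond month 24 the hazard defaults to 0 —
  follow-up gives little information on later surgeries — and is
  configurable.
* **Tunnel.** The recovery dwell is exact, encoded as expanded
  sub-states (default 1 month, matching the generator's short
  post-operative dip at monthly resolution).
* **Utilities and costs.** Defaults are aligned with the generator:
  *NoSurgery* 0.70, *Recovery* 0.60, *Resolved* = *Persist* 0.73 —
  equal by assumption, so the probability of resolution
  (`p_resolved`, default 0.6, i.e. up to 40% with persisting
  symptoms) cannot move QALY totals, a property the tests assert.
  The surgical episode cost (£2900) bundles the episode, mean theatre
  time and mean stay at the fixture unit costs; monthly state costs
  are small maintenance amounts. A time-varying `utility_schedule`
  (e.g. trial-informed utilities up to month 48) can override state
  utilities for the first cycles.
* **Accrual and discounting.** Start-of-cycle occupancy accrues
  utility/cost; an optional half-cycle correction averages start and
  end occupancy (off by default — monthly cycles make the bias
  small). Cycle $k$ is discounted by the factor of year
  $\lceil k/12 \rceil$, matching the within-trial convention.
* **Mortality.** A single sex-mix-weighted cohort rather than two
  stratified cohorts, matching the single-cohort model description;
  the annual probability at the cohort's current integer age is
  converted to monthly by $1-(1-q)^{1/12}$. The bundled life table is
  a synthetic Gompertz-shaped fixture covering ages 40–100, monotone
  in age within sex.

Because the emulated trial publishes neither transition
probabilities, state utilities nor state costs, the model defaults
are calibrated to its observable margins only; published 10-year
totals are structural reference points, not reproduction targets.
With the generator-aligned utility gap of 0.03 between untreated and
post-surgical states, the default extrapolation attributes a larger
10-year QALY loss to CM than the emulated analysis did — the
published base case behaves as if the long-run gap were smaller. The
`utility_schedule` mechanism is the lever for such scenarios.

**PSA.** `run_psa()` samples beta distributions for probabilities,
gamma for costs, and beta rescaled to $[-0.59,1]$ for utilities, all
method-of-moments fitted from mean and s.e.; draws are shared between
strategies unless a parameter is declared strategy-specific, and a
zero s.e. collapses a parameter to its mean.

**Validation oracle.** `microsim_oracle()` pushes individuals through
the same per-cycle probabilities and accrues the same rewards; the
cohort totals must sit within Monte-Carlo error of the
microsimulation means. This catches bookkeeping errors (tunnel
off-by-one, accrual timing, episode-cost flow) that aggregate matrix
algebra can silently absorb.

## Numerical conventions and degenerate inputs

* Utilities are validated against the SF-6D floor $-0.59$ everywhere;
  imputed values are clamped to the range.
* A zero incremental QALY yields a *flagged undefined* ICER, never an
  exception; quadrant labels handle boundary signs (a free gain is
  `dominant` with ICER 0).
* Transition rows sum to exactly 1 by construction (the diagonal takes
  the remainder); a surgery hazard plus mortality exceeding 1 is a
  specification error naming the cycle.
* Chained-equation regressions add a $10^{-8}$ ridge before the
  Cholesky factorisation to survive rank-deficient resamples; a visit
  column with no observed values is an explicit imputation error.
* Bootstrap resamples whose model fails to fit are redrawn; more than
  1% redraws aborts the run.
* All randomness flows through explicit integer seeds, and every
  seeded function restores the caller's RNG state.

## Problem sizes used by the test suite

The packaged checks run parameter recovery with 200 replicates of the
full trial size (217 per arm; `m` = 20 imputations, `B` = 200
bootstrap draws per replicate), generator-versus-truth convergence
with 400 cohorts, and cohort-versus-microsimulation equivalence with
100 000 individuals per specification — sizes at which Monte-Carlo
error is small enough for 3-standard-error checks to be meaningful
while a full run stays comfortably on a laptop.

## Known limitations

* Costs derive from a six-item ledger; there is no casemix (HRG)
  grouping, and the fixture prices are illustrative.
* The SF-6D scoring algorithm is out of scope; utilities enter as
  numbers.
* The cohort model carries no patient-level heterogeneity (that is
  the microsimulation's role) and, by default, no surgeries beyond
  month 24.
* "Credible interval" in the emulated trial's table is read as a
  percentile bootstrap interval; other interval constructions would
  need the original analysis plan.
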