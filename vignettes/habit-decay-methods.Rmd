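---
title: "Modelling habit decay from daily diary data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling habit decay from daily diary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitdecay)
```

## The problem

When a person deliberately tries to break a habit — quit snacking in front of
the TV, stop the after-dinner cigarette — how does the strength of that habit
decline day by day, and when does the decline level off? `habitdecay`
analyses intensive longitudinal data designed for that question: each
participant answers a short end-of-day e-diary for up to 84 consecutive days,
reporting the Self-Report Behavioral Automaticity Index (SRBAI), the mean of
four 0–4 items measuring how automatic the cued behaviour feels. The analysis
is idiographic first: every participant gets their own trajectory model, and
group-level conclusions are built on top of the person-specific results.

## Preprocessing

Raw diary exports are messy in predictable ways, and each cleaning rule is a
separate, tested operation:

* **After-midnight recoding.** An "end of day" questionnaire answered at
  02:30 refers to the day that just ended, so any response with clock time in
  the half-open interval [00:00, 12:00) is assigned to the previous calendar
  day. Noon itself belongs to its own day.
* **Duplicate averaging.** Multiple responses for the same participant-day
  are collapsed to the arithmetic mean of their SRBAI scores.
* **Scoring.** The SRBAI is the mean of four integer items; rows with a
  missing item are rejected rather than partially scored.
* **Singleton imputation.** Only a missing day whose two immediate
  neighbours are both observed is filled, with the neighbour mean (for a
  single interior point this equals linear interpolation, so the choice
  agrees with any linear scheme on singleton gaps). Runs of two or more
  missing days — "missing gaps" — and edge-missing days are retained as
  missing. Imputation therefore never creates data inside the gaps that the
  validity gate later inspects.
* **Retention.** A participant enters the analysis with at least six
  observed (pre-imputation) measurements and a last observation at or past
  the midpoint of the decay phase (occasion 41 of 0–83 by default; both
  thresholds are arguments).

Occasions are indexed t = 0…83, one unit per day, with the baseline
measurement kept out of the modelled series.

## Person-specific trajectory models

Six families are fitted per participant, habit strength on time, with no
autoregressive term (the aim is to describe the shape of the trajectory, not
one-step prediction):

| family | f(t) | mean parameters |
|---|---|---|
| constant | $\beta_0$ | 1 |
| linear | $\beta_0 + \beta_1 t$ | 2 |
| quadratic | $+\ \beta_2 t^2$ | 3 |
| cubic | $+\ \beta_3 t^3$ | 4 |
| asymptotic | $A + (R_0 - A)\,e^{-e^{\lambda} t}$ | 3 |
| logistic | $L + (U - L)\,/\,(1 + e^{(t-m)/s})$ | 4 |

The asymptotic curve starts at $R_0$ and approaches the asymptote $A$ at
rate $e^{\lambda}$; the log-rate parameterization keeps the rate positive
without a constraint. The logistic is four-parameter — a distinct lower
asymptote $L$ is needed because stabilization is later defined against the
lower asymptote — with $s > 0$ and the direction of change carried by the
order of $U$ and $L$, so relapse (increasing) trajectories remain
representable. A three-parameter logistic with $L = 0$ can be emulated by
fixing the prior, but is not the default.

Polynomials are solved by exact OLS. The nonlinear families use bounded
nonlinear least squares (`nls` "port"; `optim`/L-BFGS-B as fallback) from a
deterministic nine-point start grid: levels from the means of the first and
last five observations, shape parameters from a fixed coarse grid. The best
SSE wins and ties keep the earliest start, so refits are exactly
reproducible without stochastic restarts. Bounds ($A, L, U, R_0 \in [-1,5]$,
rate $\in [10^{-4}, 2]$, $m \in [-30, 120]$, $s \in [0.25, 60]$) keep curves
near the response scale while tolerating boundary-flat fits.

**Model selection** uses the Gaussian-likelihood BIC,
$n \log(\mathrm{SSE}/n) + k \log n$ with $k$ = mean parameters + 1 (error
variance counted). The SSE is floored at $10^{-10}$ so perfect fits keep a
finite BIC; since every floored fit hits the same floor, competition among
exact fits falls back to the parsimony penalty, which is what makes the
noise-free recovery suite select the generating family in all six cases.
Remaining ties (within $10^{-9}$) go to the smaller family, then the fixed
family order.

## The validity gate

Fitted values are accepted as a valid description of a trajectory only if
four checks pass:

1. **Decreasing:** fitted value at the first observed occasion exceeds that
   at the last. The comparison uses fitted values, not raw data, because the
   gate judges the model's description. Constant fits are handled separately:
   "habit stayed stable" is a meaningful verdict, judged on steps 2–4 only
   and reported as `stable_habit_valid`.
2. **Selection stability:** every observed occasion is deleted in turn, all
   families refitted, and the BIC winner recomputed. The default rule
   demands unanimity across all single-deletion replicates — the strictest
   reading of "selection not driven by individual observations" — with a
   95%-agreement alternative behind an argument. Warm starts (the full-data
   estimate plus the data-driven start) make the refits tractable; the full
   grid is available via `warm_start = FALSE`.
3. **RMSE ≤ 0.33**, inclusive at the boundary.
4. **Longest missing gap ≤ 21 days**, inclusive, measured on post-imputation
   runs (imputation only fills singletons, so gaps are unaffected).

## Time for decay to stabilize

Three operationalizations, all confined to the observed window (no
extrapolation; an out-of-window solution is reported as `NA` with
`within_window = FALSE`):

* **asymptote95** (asymptotic/logistic fits): the day 95% of the total drop
  from $f(0)$ to the lower asymptote is completed. Closed forms:
  $t^* = \ln(20)\,e^{-\lambda}$ for the asymptotic family and
  $t^* = m + s \ln\!\big(20(1 + e^{-m/s}) - 1\big)$ for the logistic; both
  are property-tested against a numeric root-finder. Days are reported as
  $\lceil t^* \rceil$, matching "reached by day d" semantics in integer
  days. Measuring the logistic drop from $f(0)$ rather than from $U$ is a
  choice; the $U$-based variant ($t^* = m + s\ln 19$) sits behind the
  `from` argument.
* **window7** (polynomial fits; computable for all): the first day t with
  $|f(t+6) - f(t)| <$ threshold, endpoints of a 7-day window rather than
  max−min within it. The threshold defaults to 0.1 with 0.01 as the stricter
  alternative — both thresholds are defensible readings of "change smaller
  than a tenth/hundredth of a scale point per week", so both are exposed and
  echoed into the run metadata.
* **midpoint crossing:** the first day the fitted value drops below 2.0, the
  midpoint of the 0–4 scale; crossing before stabilization marks a
  substantial change in habit strength.

Summaries report median (min, max) days per method × family, restricted to
valid fits whose fitted values cross the midpoint.

## Group-level models

* **Variance decomposition:** the random-intercept-only model gives the ICC,
  the share of variance due to between-person differences. Degenerate inputs
  (no within- or no between-person variance) are flagged rather than
  silently absorbed.
* **Cubic growth model:** fixed cubic polynomial in time rescaled to
  [0, 1.72] (the affine rescaling improves convergence and provably leaves
  fitted values unchanged — the coefficients transform exactly), random
  effects added iteratively from intercept to full cubic, all by ML so BICs
  are comparable across fixed-effect structures; singular covariance fits
  are flagged and retained. Group differences use a dichotomous focal-group
  indicator (one group against the average of the others, one model per
  group), optionally interacted with the time terms.
* **Asymptotic multilevel model:** estimated by a deliberate two-stage
  design — person-wise bounded NLS, then precision-weighted means for the
  fixed effects and a moment estimator (between-person covariance minus the
  average sampling covariance, projected to positive semi-definite) for the
  random effects. A full nonlinear mixed model is fragile exactly where this
  model is interesting (random effects on all three parameters); the
  two-stage estimator is deterministic, testable, and transparent about
  stage-1 failures, declaring the model non-estimable above a 50% failure
  rate. Lag-1 residual autocorrelation is reported as a diagnostic but not
  modelled.

## The synthetic cohort

Because the package must be testable without any particular study's data,
`simulate_cohort()` generates diary data with known ground truth: 194
participants in groups of 46/57/52/39, a family mix dominated by asymptotic
and logistic decay, parameters drawn from priors that keep latent curves on
the 0–4 scale, per-participant Gaussian noise (SD 0.15–0.45), and the
observation process layered on top — values rounded to the nearest 0.25
(the mean of four integer items) and clamped, ~13% isolated missing days
plus 0–3 gap blocks of geometric length (mean 11 days) starting in the
second half with probability 0.7, 2% same-day duplicates, 6% after-midnight
responses. These rates were calibrated once so that a default cohort shows
roughly 29% missing data and ~6 imputed values per participant after
retention, and group differences enter through the level parameters only.
A small fraction (5%) of asymptotic/logistic participants get non-decaying
(relapse) trajectories.

The generator emulates the *structure* of real diary data, not its full
psychology: noise is Gaussian and homoscedastic, missingness is independent
of habit strength (no "missing because disengaged" mechanism), and the true
trajectories really are one of the six families. Passing recovery tests
therefore demonstrates that the pipeline is correct and well-calibrated on
data of this structure — not that the six families exhaust real habit decay.

Ground-truth stabilization days come from the noiseless closed form, so
recovery tests have an exact target.

## Numerical choices and degenerate inputs

* SSE floor $10^{-10}$ in the BIC; BIC ties broken by parsimony then family
  order.
* Retention thresholds, RMSE and gap cut-offs, the window threshold and the
  midpoint are all arguments and are echoed into the run metadata of every
  pipeline run.
* A family with fewer than (mean parameters + 2) usable occasions is marked
  unfittable and excluded from selection; a participant with no converged
  family is flagged unmodellable.
* Empty cohorts, all-constant series, and zero-variance inputs return empty
  tables or flagged boundary results rather than errors.

## Problem sizes

The bundled tests run the full pipeline on cohorts of 12–24 synthetic
participants, recovery simulations at 100 replicates, and mixed-model
simulations at 120–200 participants × 84 occasions; the analysis scripts and
the acceptance script run the full 194-participant default cohort,
leave-one-out gate included.

## Known limitations

* The leave-one-out unanimity rule is the strictest of several defensible
  operationalizations of selection stability; with long series it is also
  conservative (84 replicates give many chances to flip a marginal
  selection).
* The two-stage asymptotic estimator recovers fixed effects well but its
  standard errors are approximate (between + sampling variance over N); a
  full-likelihood nonlinear mixed model can be substituted where it
  converges.
* Singleton-only imputation is deliberately minimal; model-based imputation
  of long gaps is out of scope, and gaps instead feed the validity gate.
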