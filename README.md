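# habitdecay

Idiographic and multilevel modelling of habit decay from daily diary data.

## What this package is for

People trying to break an everyday habit — sitting too much, snacking,
drinking, smoking — can report each evening how automatic the habitual
response still feels, using the Self-Report Behavioral Automaticity Index
(SRBAI: four 0–4 items averaged into a daily habit-strength score). Over an
84-day decay phase this yields one noisy, gappy time series per person.
`habitdecay` answers, for each person and for the cohort: *what shape does
the decline take, is the fitted description trustworthy, and when does the
decay stabilize?*

The core of the package:

* **Six person-specific trajectory families** fitted to each participant's
  series — constant, linear, quadratic, cubic, the asymptotic decay
  f(t) = A + (R₀ − A)·e^(−e^λ·t), and the four-parameter logistic
  f(t) = L + (U − L)/(1 + e^((t−m)/s)) — compared by the
  Gaussian-likelihood BIC, n·ln(SSE/n) + k·ln(n).
* **A 4-step validity gate** on the best-fitting model: (1) decreasing
  fitted trajectory, (2) BIC selection unchanged under every single-occasion
  deletion (leave-one-out stability), (3) RMSE ≤ 0.33, (4) no missing gap
  longer than 21 days.
* **Three stabilization estimators**, strictly within the observed window:
  the day 95 % of the drop to the lower asymptote is completed
  (closed form t\* = ln(20)·e^(−λ) for the asymptotic family), the first day
  the fitted change over a 7-day window falls below 0.1, and the first day
  fitted values cross the scale midpoint 2.0.
* **Group-level mixed models**: the constant-model ICC, cubic growth models
  on time rescaled to [0, 1.72] with an iterative random-effect ladder and
  dichotomous behavioural-group contrasts, and a two-stage asymptotic
  multilevel estimator.
* **A seeded synthetic cohort generator** that emulates the structure of
  such diary studies (194 participants in groups of 46/57/52/39, ≈29 %
  missing values with late-series gaps, same-day duplicates, after-midnight
  responses) with known ground truth, so every stage is testable.

## Worked example

```r
library(habitdecay)

cfg <- cohort_config(group_sizes = c(SB = 5L, US = 5L, AC = 5L, TS = 5L),
                     seed = 7L)
res <- run_pipeline(cfg, loo = TRUE)

res$summary$best_family_freq
#>       family n pct
#> 1 asymptotic 9  45
#> 2   constant 1   5
#> 3      cubic 1   5
#> 4     linear 3  15
#> 5   logistic 5  25
#> 6  quadratic 1   5

res$summary$n_overall_valid        # 8 valid decaying trajectories
res$summary$n_stable_habit_valid   # 1 valid "habit stayed stable" (constant)

stab <- res$stabilization_summary
stab[stab$n > 0 & stab$method == "asymptote95", ]
#>         method     family n median min max
#> 17 asymptote95 asymptotic 4     21  10  70
#> 18 asymptote95   logistic 3     51  33  60

round(res$summary$multilevel$icc, 2)
#> [1] 0.53
```

Reading the output: 14 of the 20 simulated participants are best described
by one of the bounded decay curves (asymptotic or logistic); 8 participants
pass all four validity checks, and among the valid asymptotic fits the decay
had completed 95 % of its drop after a median of 21 days (range 10–70). The
ICC says 53 % of the variance in this small cohort is between-person.

## The analysis workflow

The `analysis/` directory holds the pipeline as numbered drivers over the
package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic cohort + ground truth
Rscript analysis/02_preprocess.R    # cleaning, imputation, retention
Rscript analysis/03_person_models.R # six-family fits + validity gate
Rscript analysis/04_stabilization.R # stabilization days + summary table
Rscript analysis/05_multilevel.R    # ICC, cubic ladder, group contrasts
```

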