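# progdelay

Treatment effects in progressive diseases are conventionally reported as a
difference in scale points after 18–36 months — a number with little
intrinsic meaning to patients.  `progdelay` is a simulation laboratory for
the alternative: estimating the effect as a **delay of disease progression
in units of time**, and carrying that delay into long-term outcomes.

The package simulates two-arm trials on the CDR-SB scale (Clinical Dementia
Rating – Sum of Boxes, 0–18, higher is worse) for an amyloid-positive MCI
population, and compares three analyses of the same data:

- **Time-based PMRM** (progression model for repeated measures).  Subject
  vectors are multivariate normal with unstructured covariance Σ; placebo
  means α_j are free per visit, and the active arm's mean at visit t_j is
  g(t_j − Δ_j), where g is the natural-spline interpolant of the placebo
  means.  The per-visit delays Δ_j (months) — and the percent slowing
  Δ_j/t_j — are the treatment effect, estimated by maximum likelihood with
  the covariance profiled out in closed form.
- **MMRM-style cLDA**: shared baseline, free arm-by-visit means,
  unstructured covariance; the effect is the placebo-minus-active
  change-from-baseline difference at the final visit (points, and percent
  of the placebo change).
- **Cox proportional hazards** on progression to dementia, dichotomized as
  first post-baseline visit with CDR-SB ≥ 4.5 (Efron ties).

A replication harness sweeps sample size × duration scenarios for median
effects and empirical power, and a four-state Markov cohort model (MCI →
mild dementia → moderate-to-severe dementia → death, monthly cycles over 15
years) translates an estimated slowing s into state-occupancy outcomes by
**stretching the treatment arm's time axis**: the treated cohort traverses
the placebo trace while cycle k ends at (1+s)·k months.

## Worked example

Simulate one 36-month trial (700 per arm, true slowing 20%) and read the
effect three ways:

```r
library(progdelay)
traj  <- default_trajectory()                      # packaged synthetic fixture
trial <- generate_trial(traj, slowing_fraction = 0.20,
                        n_per_arm = 700, duration_months = 36, seed = 1)
fit_pmrm(trial)
#> Time-based PMRM fit (700 placebo / 700 active subjects)
#>                   m6   m12   m18   m24   m36
#> delay (months)  0.95  3.49  5.02  5.56  8.06
#> SE              0.81  0.73  0.92  0.96  1.18
#> % slowing      15.88 29.08 27.90 23.18 22.38
#> log-likelihood: -10830.53
#> Wald p (final visit delay): 8.5498e-12
fit_mmrm(trial)
#> final-visit CFB difference (placebo - active): 0.731 points (SE 0.118)
#> percent reduction in CFB: 28.6%
fit_cox(dichotomize_progression(trial))
#> Cox fit (efron ties): HR 0.690 (log HR -0.371, SE 0.085), p 1.3038e-05
```

The PMRM reads this trial as an 8.1-month delay at month 36 (22% slowing,
true value 20%); the score-scale model reads the same data as a 0.73-point
(29%) reduction — larger than 20% because the decline is convex — and the
Cox model as a hazard ratio of 0.69.  Feeding the fitted slowing into the
Markov model:

```r
spec <- markov_spec(slowing_fraction = from_pmrm(fit_pmrm(trial), rounded = TRUE))
run_placebo(spec)$overall_survival              # 110.6 months
run_treatment_time_stretch(spec)$overall_survival   # 122.5 months
```

a persistent 22% slowing buys about a year of life expectancy within the
15-year horizon, concentrated in the milder states.

Scenario sweeps use the harness:

```r
res <- run_study(scenario_grid(n_replicates = 200), traj, 0.20)
render_tables(res)    # Table-style medians (whole %, HR to 2 decimals) + power
```

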