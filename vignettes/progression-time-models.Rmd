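---
title: "Measuring treatment effects as time: simulation models and a Markov translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring treatment effects as time: simulation models and a Markov translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progdelay)
```

## The scientific problem

Disease-modifying treatments in Alzheimer's disease are expected to slow
progression, with benefits that accumulate over years, yet trials report
effects as point differences on clinical scales after 18--36 months.  A
half-point difference on the CDR-SB (Clinical Dementia Rating, Sum of Boxes;
0--18, higher is worse) is hard to interpret.  Expressing the same effect on
the *time* axis — "the treated arm is where the placebo arm was seven months
ago" — is far more tangible, and it maps directly onto the machinery of
health-economic models, which reason about how long patients spend in each
disease stage.

This package provides a complete simulation laboratory for that idea:

1. a generator of two-arm trial datasets with a known proportional slowing
   of progression;
2. the time-based progression model for repeated measures (PMRM), which
   estimates per-visit time delays;
3. two conventional comparators — a constrained longitudinal (MMRM-style)
   model estimating score-scale differences, and a Cox model on dichotomized
   progression to dementia;
4. a replication harness for median effects and empirical power over
   scenario grids; and
5. a four-state Markov cohort model that converts an estimated slowing into
   long-term time in state by stretching the treatment arm's time axis.

## The generative model

Each subject contributes a CDR-SB vector over scheduled visits (months 0, 6,
12, 18, 24, 36 by default), drawn from a multivariate normal distribution
with an unstructured $J \times J$ covariance $\Sigma$ shared by the arms.
Placebo subjects are centred on per-visit means $\alpha_j$; active subjects
at visit $t_j$ are centred on the placebo mean curve evaluated at
$(1-s)\,t_j$, using **linear** interpolation between visits, where
$s$ is the true proportional slowing (default 0.20).  With a worsening
trajectory this pushes the active arm's expectation down by an amount that
grows with the local slope, so a constant fractional time delay produces a
*shape-dependent* vertical effect — the central phenomenon the three
analysis models read differently.

Deliberate simplifications: scores stay continuous (no rounding to the
instrument's half-point grid, no truncation at 0 or 18) and there is no
dropout, so every subject is observed at every visit.  Both choices keep the
generative law exactly inside the PMRM/MMRM likelihood families; passing
tests therefore demonstrate correctness of the estimators under their own
assumptions, not robustness to the missingness and floor/ceiling effects of
real trials.

### The packaged trajectory fixture

Estimated visit means and covariances from real cohorts are rarely public,
so the package ships a synthetic fixture (`default_trajectory()`)
emulating an amyloid-positive MCI population: baseline mean 1.5 points
(matching the typical median severity of such cohorts), change from
baseline (0, 0.15, 0.45, 0.90, 1.45, 2.55) points, standard deviations
rising from 1.0 to 2.6 points, and correlations
$0.3 + 0.7 \cdot 0.85^{\Delta t / 6}$.  The shape accelerates early and
becomes steep and nearly linear between months 24 and 36, the pattern
published estimates of early-AD CDR-SB progression show; it also controls
the small systematic discrepancy between the linear interpolation used in
generation and the spline inversion used in fitting (see below), which is
what makes the estimated percent delay land near 19% at month 18 but 20% at
month 36.  All values can be overridden through `trajectory_spec()` or a
YAML configuration (`read_trial_config()`), so users holding estimated
cohort values can substitute them without touching code.

## The time-based PMRM

Let $g$ be the natural cubic spline through $(t_j, \alpha_j)$, extrapolated
linearly with the boundary slope.  The model is

$$y_i \sim \mathcal{N}(\mu_{a(i)}, \Sigma), \qquad
\mu_{\text{placebo},j} = \alpha_j, \qquad
\mu_{\text{active},j} = g(t_j - \Delta_j),$$

with $\Delta_0 = 0$ at baseline (randomization guarantees equal means at
month 0) and one free delay $\Delta_j$ (months) per post-baseline visit —
no proportionality across visits is assumed.  The percent slowing at visit
$j$ is $\Delta_j / t_j$.  The spline is the model's way of *borrowing the
whole placebo time course* when reading off a horizontal displacement,
which is also the intuition for its small power advantage over the
score-scale model.

Numerical strategy, chosen for this package:

* **Profiled covariance.** For fixed means the ML covariance is the pooled
  residual covariance; because all subjects in an arm share a mean, the
  profile objective depends on the data only through the per-arm mean
  vectors and a fixed within-arm scatter, making each evaluation $O(J^2)$
  regardless of sample size.  Optimization is over the $2J-1$ mean
  parameters only.
* **Analytic gradients.** The spline value is linear in the knot values, so
  the gradient needs only the cardinal-basis weights and the spline slope at
  the warped times; both come from the same second-derivative representation.
* **Multi-start quasi-Newton.** L-BFGS-B from three starts ($\alpha$ at the
  placebo visit means, delays at proportional slowings selected from the
  grid $\{0, 10\%, 20\%, 30\%\}$), relative convergence $10^{-8}$, bound
  $|\Delta_j| \le t_j$ so the active arm is never warped to before baseline.
  The bound can bind at early visits in small samples, where a month-scale
  delay is weakly identified against a nearly flat early curve; the
  final-visit delay, the primary estimand, is unaffected.
* **Maximum likelihood, not REML.** At the sample sizes of interest
  ($\ge 200$/arm) the variance bias of ML is negligible; ML keeps the
  profiled objective exact.
* **Inference.** Standard errors from the inverse observed information of
  the profile likelihood (its curvature equals the corresponding Schur
  complement of the full information).  The "treatment detected" event is a
  two-sided Wald test of $\Delta$ at the final visit at $\alpha = 0.05$.
* **Degenerate inputs.** Noise-free datasets (zero covariance) make the
  scatter singular; a tiny fixed ridge ($10^{-8}$) keeps the profile defined
  and the fit then interpolates the group means exactly.  A non-monotone
  fitted reference curve triggers a warning but not an error: the warp
  remains defined.

An identity worth knowing: with saturated per-visit delays the PMRM mean
manifold coincides locally with that of the shared-baseline MMRM (both have
a shared baseline, free placebo means, and five freely adjustable active
means), so the two ML fits agree on fitted means and likelihood.  The
models differ in the *parameterization* — horizontal versus vertical — and
hence in the Wald statistics their effect scales produce.  The test suite
exploits this as a cross-check.

### Linear generation versus spline fitting

Generation warps the mean curve with linear interpolation; fitting inverts
a spline.  The two interpolants differ between knots, so even noise-free
data yield percent delays that deviate from the generative 20% by a few
tenths of a point (more at early visits, where the delay is measured
against a small $t_j$ and a flat curve).  This mismatch is intentional —
the simulated truth and the analysis model are specified independently —
and is documented rather than removed.

## The comparators

**MMRM (cLDA).** The default score-scale model is the constrained
longitudinal data analysis: a shared baseline mean, free arm-by-visit means
after baseline, unstructured common covariance, ML via iterative GLS (the
two conditional updates are each closed-form).  Reported effect: the
placebo-minus-active difference in change from baseline at the final visit,
and that difference as a fraction of the placebo change.  A classic
CFB-outcome MMRM with baseline-by-visit covariate adjustment is available
(`method = "cfb"`) as a conventional alternative; with a common design
across coordinates its ML mean estimate reduces to multivariate OLS.

**Cox on dichotomized progression.** Progression to dementia is defined as
the first post-baseline visit with CDR-SB $\ge 4.5$; never-crossers are
censored at the last visit.  Baseline values never count as events, even
above threshold (possible under unclipped simulation).  Events sit on at
most five discrete times, so ties are heavy: Efron's approximation is the
default (Breslow is noticeably biased at this tie density and is available
as a switch).  Events are placed at visit times with no interval-censoring
correction, a deliberate simplification mirroring common practice.  The
dichotomization discards the scale's granularity and the repeated measures,
which is exactly why this model needs the largest sample sizes.

## The replication harness

`run_study()` sweeps scenarios (defaults: 200--700 subjects/arm by 18/24/36
months), generating `n_replicates` trials per scenario and fitting all
three models to each.  Per-replicate seeds are derived deterministically
from the master seed and the scenario index, so results are reproducible
and independent of execution order.  Medians are taken over converged fits
only, with convergence rates reported and a hard failure (by default) if
any scenario's rate drops below 95%.  The desk default of 200 replicates
gives a Monte-Carlo error around one percentage point on a median effect
and 0.03--0.04 on a power estimate; the package's own acceptance checks use
200 replicates for the median-recovery result and 500 for power ordering,
sizes chosen to make those specific contrasts decisive at desk scale.
Publication-grade tables would use 1000.

## The Markov health-economic model

Four states — MCI due to AD, mild AD dementia, moderate-to-severe AD
dementia, death — in monthly cycles over 15 years, whole cohort starting in
MCI, no back-transitions, constant intensities.  Monthly mortality is
0.3%, 0.5% and 1.0% in the three alive states; annual progression
probabilities of 23% (MCI to mild) and 39% (mild to moderate-to-severe)
convert to monthly via $1 - (1-p)^{1/12}$.  Time in state integrates
occupancy with half-cycle correction (first and last cycle weighted one
half, the standard trapezoid).

**Within-cycle ordering.** With death and progression competing inside a
cycle the literature leaves the ordering open.  This package applies death
first and progression to survivors — $P(\text{MCI} \to \text{mild}) =
(1 - 0.003) \times (1 - 0.77^{1/12})$ — as its fixed default; the reverse
ordering is available via `ordering = "progression_first"`.  The orderings
differ by about half a month of restricted survival, enough to move a
whole-month rounding.

**The time-stretched treatment arm.** Rather than applying a hazard
reduction to transition probabilities (the vertical convention), the
treatment arm traverses the *same* occupancy trace as placebo while each
cycle lasts $(1+s)$ months, ending at $(1+s)k$ — the horizontal convention,
matching an effect estimated as a slowing.  The slowing persists over the
whole horizon and hence implicitly delays death as well; there is no
separate mortality-effect parameter.  Outcomes integrate occupancy against
the stretched cycle lengths truncated at the 180-month horizon (the
straddling cycle contributes its within-horizon fraction).  Setting the
horizon far beyond the cohort's survival removes truncation, where every
state time must scale exactly by $(1+s)$ — the oracle the tests use to pin
the stretch logic.

With the default 19% stretch (the kind of estimate an 18-month trial's
PMRM fit delivers, cf. `from_pmrm()`):

```{r markov}
spec <- markov_spec()
placebo <- run_placebo(spec)
treated <- run_treatment_time_stretch(spec)
round(rbind(placebo = c(placebo$time_in_state, os = placebo$overall_survival),
            treated = c(treated$time_in_state, os = treated$overall_survival)), 1)
```

Survival rises by about ten months, with the gain concentrated in MCI
(about seven months) and mild dementia (about three): stretching time adds
life without adding time in the severe state within the horizon.

## Worked example

```{r example}
traj <- default_trajectory()
trial <- generate_trial(traj, slowing_fraction = 0.20,
                        n_per_arm = 700, duration_months = 36, seed = 1)
fit <- fit_pmrm(trial)
fit
round(100 * unlist(delay_confidence_interval(fit, 36)[c("percent_lower",
                                                        "percent_upper")]), 1)
fit_mmrm(trial)
fit_cox(dichotomize_progression(trial))
```

One simulated trial of 700 per arm: the PMRM reads the effect as a delay of
months at month 36, the MMRM as a fraction of the placebo worsening
(larger than 20% because the decline is convex), and the Cox model as a
hazard ratio below one — three renderings of the same underlying 20%
slowing.

## Known limitations

* The fixture is synthetic; absolute power numbers and the MMRM/Cox effect
  magnitudes depend on the trajectory shape and transfer to real cohorts
  only qualitatively.  (The PMRM percent-delay median does not: the
  generative truth pins it at the slowing used.)
* No dropout, no score discretization, no floor/ceiling: estimator
  robustness to those is untested here.
* Only the proportional-slowing effect shape is simulated; treatment
  effects that plateau or act only on some visits are out of scope.
* The Markov model tracks time in state only — no costs, utilities or
  discounting — and assumes the estimated slowing persists for 15 years.
* ML (not REML) covariance estimates are biased low in small samples;
  at 200+ subjects per arm this is immaterial, but do not use the fits for
  n of a few dozen without adjusting expectations.
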