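---
title: "Predictive probabilities from interim-analysis announcements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive probabilities from interim-analysis announcements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When the monitoring committee of a group-sequential trial announces only
"the trial continues", outside observers still learn something: the data
crossed neither the efficacy nor the futility boundary, so the experimental
arm is neither dramatically effective nor hopeless. `gspred` turns that
qualitative statement into numbers for a two-arm survival trial. Its worked
default is the NSABP C-08 adjuvant colon-cancer trial (bevacizumab added to
mFOLFOX6), whose monitoring plan was public: 2,632 patients, a one-sided
log-rank test, six planned interims with asymmetric one-sided boundaries,
and a final analysis at 592 disease-free-survival (DFS) events at one-sided
level 0.0246.

The quantity of interest is *predictive power*: the probability of eventual
trial success averaged over a distribution of treatment effects, as opposed
to power at one assumed effect (traditional power) or success probability
given interim data under one assumed effect (conditional power). Before the
trial the averaging distribution is a prior; after each "continue"
announcement it is the posterior given the event "no boundary crossed so
far".

## The model

**Treatment effect.** The effect is the hazard reduction $\delta = 1 -
\text{HR}$ on the proportional-hazards scale. The practical range is 0-40%,
discretized in 5% steps; a prior is a non-negative weight per grid point,
and only relative weights matter.

**Event times.** Control-arm DFS times are piecewise exponential with
hazard 0.089/year for the first three years after randomization and
0.039/year thereafter (the protocol's assumption: recurrence risk is
front-loaded). Experimental-arm times use the same cumulative hazard scaled
by $1 - \delta$. Sampling inverts $S(t) = \exp\{-(1-\delta)H(t)\}$ exactly.

**Accrual.** The monthly accrual rate ramps linearly from 63 to 105
patients over 24 months and stays at 105 until 2,632 patients are enrolled
(month 29.9). Entry times are drawn by inverting the cumulative accrual
curve at uniform quantiles; allocation is exactly 1:1 by alternation in
entry order, which removes binomial noise in the arm sizes without changing
any estimand. The published plan prints an expected 2,006 enrolled at two
years, while the linear ramp integrates to 2,016; the exact ramp shape was
never published, and we keep the linear ramp rather than force agreement.

**Monitoring.** Interim 1 triggers at the 148th event; interims 2-6 at
calendar years 2.5-4.5 (the published event counts for those analyses are
estimates, not triggers); the final analysis at the 592nd event. At each
interim the two-sample log-rank statistic $z = (O_c - E_c)/\sqrt{V}$ is
standardized with the hypergeometric variance over distinct event times;
$p_{\text{left}} = 1 - \Phi(z)$ is compared to the efficacy bound and
$p_{\text{right}} = \Phi(z)$ to the futility bound, both strictly
("stop if $P <$ bound"). Superiority is checked first, though the
asymmetric bounds make simultaneous crossing impossible. A degenerate
snapshot (no events, or single-arm risk sets) yields no test and maps to
"continue" - a committee cannot cross a boundary without a statistic. If
events outpace the calendar so that the 592nd event precedes a scheduled
interim, that interim is skipped, as happened in the real trial (four
interims instead of six). Simulated trials are followed to their 592nd
event with no administrative censoring horizon: the exponential tail
guarantees the events arrive, and the protocol's "5 years" was an
expectation rather than a rule.

**Outcome tables.** For each $\delta$ on the grid, `estimate_outcome_table()`
runs many independent replicates and tabulates $P(\text{superiority stop at }k)$,
$P(\text{futility stop at }k)$, $P(\text{final success})$ and
$P(\text{final fail})$. The counts partition the replicates, so the
probabilities sum to one exactly - several identities downstream rely on
this.

**Mixing and updating.** `predictive_report()` mixes the tables over a
prior. Unconditional rows are plain mixtures. Every conditional quantity is
a ratio of mixed joints,
$$
P(\text{outcome} \mid \text{continued through } k-1)
  = \frac{\sum_\delta w_\delta \, P(\text{outcome} \wedge \text{cont.}_{k-1} \mid \delta)}
         {\sum_\delta w_\delta \, P(\text{cont.}_{k-1} \mid \delta)},
$$
never a mixture of per-effect conditionals: conditioning re-weights the
effects to their posterior, and mixing conditionals with the *prior*
weights is the natural-looking wrong answer. The package's tests assert the
equivalence of this joint-ratio route with the explicit posterior route
(`posterior_given_continue()`, whose likelihood is the cumulative
continuation probability $P(\text{no stop at looks } 1..k \mid \delta)$).

## Worked example

```{r, eval = FALSE}
library(gspred)
design <- nsabp_c08_design()

# per-effect operating characteristics (cached; the expensive step)
tables <- sweep_effects(design, n_reps = 10000, seed = 1,
                        cache_dir = "cache")

# spreadsheet-style report under the packaged custom prior
report <- predictive_report(preset_prior("custom"), tables)
report
eventual_outcome_summary(report, k = 0)   # before the trial
eventual_outcome_summary(report, k = 3)   # after three "continue" announcements
```

## Boundary calibration

The final-look level 0.0246 printed in the plan is the solution of an
alpha-spending equation. `calibrate_final_alpha()` verifies it: under the
canonical joint normal model for sequential log-rank statistics
($\mathrm{Corr}(Z_j, Z_k) = \sqrt{t_j/t_k}$ for information fractions
$t_j \le t_k$, here event-count ratios 148/592, ..., 538/592), it solves by
bisection for the final nominal level at which the total probability of
crossing any efficacy bound is 0.025 (the conventional one-sided phase-III
total, just above the printed 0.0246). Crossing probabilities come from the
classical stage-by-stage recursion: on the Brownian scale the increments
are independent normals, so the no-crossing sub-density propagates by a
one-dimensional convolution evaluated on a trapezoid grid (2,001 points per
stage, ~1e-6 accuracy; the final stage reduces to a closed-form normal-tail
integral, which makes the bisection cheap). With the printed schedule the
calibrated level is 0.0244, within half a point of the printed ~0.0246 in
the fourth decimal. The tests cross-check the recursion against an
independent multivariate-normal quadrature on small problems, and against
the simulator itself: with futility stopping disabled, the fraction of null
trials that ever cross an efficacy bound (or win at the final level)
matches the analytic crossing probability within Monte-Carlo error. That
no-futility arrangement is the right cross-check because the spending
calculation itself ignores futility; with the futility bounds active the
full design's null success rate is very slightly lower (futility absorption),
which the property tests also assert.

## Priors

`"simple"` is exactly uniform. The other four presets - pessimistic,
moderate, optimistic, custom - reproduce belief curves that were published
only graphically, so the packaged vectors are pinned approximations; any
report quotes the exact vector used. The custom prior (weights 3, 6, 10,
10, 8, 5, 0.5, 0.1, 0 on reductions 0-40%) follows the described shape -
peaked at 10-15% reduction, negligible mass at 30% or more - and was fixed
once by checking candidate shape-conforming vectors against the published
summary probabilities; it is an approximation, and downstream numbers based
on it should be read with percentage-point, not decimal, precision.

## Numerical and design choices

* **Replicates.** The original analysis used 70,000 replicates per effect
  (the package default in `run_config()`). The packaged tests and the
  acceptance script use 5,000-50,000 so a full run stays in the minutes
  range; at 10,000 replicates the Monte-Carlo standard error of a
  probability near 0.93 is about 0.25 points.
* **Seeding.** One derived seed per (effect, replicate) pair from a
  documented splitting rule, so any single table can be recomputed
  independently and sweeps are order-independent and cacheable.
* **Ties.** Entry and event times are continuous, so ties are
  probability-zero; the log-rank nevertheless groups distinct event times
  and uses the multi-event hypergeometric variance, and the event-order
  statistic breaks exact ties by patient index.
* **Degenerate inputs.** Validation never raises (it returns messages);
  a zero stopping bound disables that kind of stop, which is how the
  no-stopping and futility-disabled designs used in the tests are
  expressed.

## What the simulator does and does not emulate

It emulates the protocol-projected trial: projected accrual, continuous
event ascertainment, proportional hazards, no dropout, and a composite DFS
event treated as a single endpoint. It does not model the real trial's 2006
accrual pause, its faster-than-planned accrual (2,710 patients), assessment-
visit ascertainment, non-proportional hazards, or loss to follow-up. Passing
tests therefore certify the method's internal identities and its agreement
with the published design's operating characteristics - not calibration to
the realized conduct of any particular trial. One consequence is visible in
the numbers: the simulated success probability at a fixed 25% reduction is
~93.5%, consistent with the Schoenfeld closed form for 592 events at level
0.0246 but above both the published simulation's 92% and the protocol's
advertised 90% power, which evidently reflect unpublished details of their
respective calculations. Quantities that average over a prior are
correspondingly shifted by a point or two.
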