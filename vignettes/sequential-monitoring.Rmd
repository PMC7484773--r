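---
title: "Sequential monitoring of two-arm binary trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential monitoring of two-arm binary trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmonitor)
```

## The problem

A two-arm randomized trial with a binary endpoint accrues participants over
time. At any interim point the data form a 2×2 table — events and non-events
by arm — and an odds ratio (OR) can be computed. If the trial is "monitored"
by recomputing an unadjusted significance test as each participant's outcome
arrives, the P value wanders: it can dip under the 0.05 line at one look and
climb back over it at the next, and the chance that it *ever* dips under the
line on null data grows far beyond the nominal 5% as looks accumulate. This
package provides the machinery to study that behaviour directly — per-look
effect trajectories, crossing detection, resampling-based trial extension —
and a Bayesian group sequential monitor that replaces repeated testing with
posterior probabilities of success and futility evaluated under a skeptical
prior, which can be checked at every look without multiplicity correction.

## Frequentist machinery

All frequentist inference is Wald inference on the log odds ratio. For a
table with cells $a$ (intervention events), $b$ (intervention non-events),
$c$ (control events), $d$ (control non-events):

$$\widehat{OR} = \frac{ad}{bc}, \qquad
  \mathrm{SE}(\log \widehat{OR}) = \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d},$$

with the $100(1-\alpha)\%$ interval $\exp(\log\widehat{OR} \pm
z_{1-\alpha/2}\,\mathrm{SE})$ and the two-sided P value from the standard
normal. The choice of the Wald test is deliberate: it makes the OR, its CI
and its P value mutually consistent (the CI is log-symmetric about the OR,
and the P value can be recovered from the CI width), which is exactly the
consistency the worked examples in the test suite verify. Likelihood-ratio
or exact conditional tests are intentionally out of scope.

Two conventions matter for trajectories:

* **Looks are indexed by responders**, not by randomized participants.
  Participants lost to follow-up contribute no outcome and do not consume a
  look slot; the `responded` flag on each record lets users index either way
  by pre-filtering.
* **Zero cells** use the Haldane–Anscombe correction: 0.5 added to *every*
  cell, applied only when some cell is zero, and flagged in the output. With
  the default look schedule starting at two responders, early tables almost
  always contain zeros; the correction keeps the trajectory defined from the
  first look instead of leaving holes. When no cell is zero the correction
  is exactly a no-op.

Significance uses strict inequality (`p < alpha`, default `alpha = 0.05`);
a P value equal to the threshold is not significant. A crossing is recorded
whenever the significance state changes between consecutive looks, and the
naive "peeking" stopping rule is simply the first look whose state is
significant. The default schedule recomputes at every responder (`step = 1`)
— the finest granularity, and the one under which peeking inflation is
largest; coarser schedules are a parameter away.

## Resampling extension

`extend_trial()` appends `n_extra` pseudo-participants drawn i.i.d. with
replacement from the observed responders. This is a thought experiment, not
an imputation method: if the new recruits look exactly like the old ones,
statistical significance eventually arrives for any sample OR different
from 1, because the SE shrinks like $1/\sqrt{n}$ while the OR stays put. By
default draws copy whole (arm, outcome) pairs, so arm sizes random-walk just
as they would under Bernoulli randomization; `stratify_by_arm = TRUE`
instead alternates arms deterministically and resamples outcomes within
arm, for users who want arm balance preserved. Non-responders are never in
the sampling pool.

## The Bayesian monitor

The monitored parameter is $\theta = \log OR$ with a normal skeptical prior,
default $\theta \sim N(0,\ 0.2^2)$ — interpreted on the log-OR scale, so the
prior is centred on "no effect" and places about 95% of its mass on ORs
between 0.68 and 1.48. Data must overcome this skepticism before the
success rule can fire.

Two posterior engines are provided:

* **Conjugate** (default): treat the observed $\log\widehat{OR}$ as normal
  with known SE and combine precisions:
  $$\sigma_{post}^{-2} = \sigma_{prior}^{-2} + \mathrm{SE}^{-2}, \qquad
    \mu_{post} = \sigma_{post}^{2}\left(\frac{\mu_{prior}}{\sigma_{prior}^{2}}
    + \frac{\log\widehat{OR}}{\mathrm{SE}^{2}}\right).$$
  It is deterministic, vectorizes over thousands of looks, and inherits the
  Haldane correction at degenerate early looks, so monitoring is defined
  from the very first look.
* **Grid** (`posterior_grid()`, `method = "grid"`): the exact two-binomial
  likelihood on a 2-D grid — uniform prior on the control event probability,
  the skeptical prior on $\theta$ — marginalized to $\theta$. No normality
  assumption. This is the oracle the conjugate engine is tested against,
  and it is the engine of choice when cell counts are small enough that the
  normal approximation is in doubt.

The approximation error of the conjugate engine is not negligible at modest
event counts: on tables with all cells ≥ 5 drawn from realistic trial
configurations, the two engines' success probabilities can differ by a few
hundredths (largest when the posterior mass straddles the decision bound),
while posterior median ORs stay within about 0.05. The test suite
characterizes this gap against the converged grid, and the grid itself is
validated against closed-form prior-only probabilities and adaptive
quadrature. MCMC is deliberately avoided — nothing in this model requires it.

The default decision rule follows the standard success/futility pattern:
stop for **success** when $P(OR > 1 \mid \text{data}) > 0.95$; stop for
**futility** when $P(1/1.25 < OR < 1.25 \mid \text{data}) > 0.95$, i.e. when
the arms are almost certainly practically equivalent. Both thresholds are
strict ("more than 95%"), success is checked before futility if both fire
at one look (arbitrary but documented; with these defaults both cannot
actually fire together), and looks cease at the first stop. Before any data
accrue, the prior itself fixes the decision state: $P(OR > 1) = 0.5$ and the
futility mass is $2\Phi(\ln 1.25 / 0.2) - 1 \approx 0.735$, so neither rule
can fire at the prior alone — the monitor cannot stop a trial that has not
started.

## Numerical choices

* Grid: 801 log-OR points spanning ±8 posterior SDs around the approximate
  posterior mean, 201 midpoint nodes for the control probability, log-space
  likelihood accumulation, and a midpoint-convention CDF interpolated
  linearly between nodes (exact at the centre of a symmetric posterior).
  If more than 1e-6 of posterior mass lands on the outermost grid rows the
  function stops and advises a wider grid rather than silently truncating.
* The conjugate engine accepts an infinite SE as "no data yet" and returns
  the prior.
* All stochastic operations take explicit integer seeds, restore the
  caller's RNG state, and record the seed in their outputs; Monte-Carlo
  runs derive per-replicate seeds as `base_seed + rep` so paired analyses
  see identical data.

## What the generator emulates — and what it does not

`simulate_trial()` produces accrual-ordered records with Bernoulli
(equal-probability by default) randomization, Bernoulli outcomes at the
configured control probability and true OR (the intervention probability is
derived exactly on the odds scale), completely-at-random attrition, and
optional regime drift: accrual segments with different control event
probabilities, with the OR held constant so the estimand is stable across
regimes. The two presets copy only the *designs* of the motivating trials —
535 participants with 30% attrition and a plausible OR of 1.6 for the
smoking-cessation stand-in; 560 participants, no attrition and a null OR
for the link-press stand-in — because the real trials' arm-level outcomes
were never published. Event probabilities (0.20 and 0.25) are in the range
typical of behavioural text-messaging interventions.

Real trials violate these idealizations in ways the generator does not
model: informative attrition, block or stratified randomization, covariate
effects, delayed outcome ascertainment, and drift affecting the effect size
itself. Passing tests therefore demonstrate correctness of the machinery
under clean conditions, not robustness of the monitoring rules to those
violations.

## Design decisions on genuinely open points

* **Calibration is assessed under a vague prior.** The parameter-recovery
  check asks whether the conjugate 95% posterior interval covers the true
  log-OR about 95% of the time. Under the skeptical prior this cannot and
  should not happen for a true OR of 1.8 at a few hundred participants —
  shrinkage toward the null is the prior's entire purpose, and it trades
  coverage at distant truths for resistance to early noise. Calibration is
  therefore computed with prior SD 10 (effectively flat), where the
  posterior interval reduces to the Wald interval; the skeptical prior's
  shrinkage and its early-look protection are asserted as separate
  properties.
* **Per-responder looks** are the default everywhere, the most demanding
  schedule for the naive rule and the natural unit of "each time new data
  is available" for the Bayesian one.
* **Unstratified resampling** is the extension default; the stratified
  variant exists because unstratified draws let arm sizes drift, which some
  users will not want in a design thought experiment.
* **Monte-Carlo problem sizes**: the operating-characteristics runs use
  1000 null trials of 500 participants with looks at every responder from
  20; calibration uses 500 trials of 535; the extension experiment uses 200
  resampling draws of 400 extra responders. These sizes give Monte-Carlo
  standard errors of about 0.7–2 percentage points on the reported rates,
  small enough to see the inflation effect clearly while keeping any single
  analysis under a few seconds on one core.

## Limitations

The monitor handles a single binary endpoint and an unadjusted OR; no
covariates, no harm-specific rules, no predictive probabilities, and no
frequentist alpha-spending corrections (the package exists to study the
contrast with them, not to implement them). The conjugate engine should not
be trusted for decision-making when any cell count is small and the
posterior sits near a decision bound — use `method = "grid"` there.
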