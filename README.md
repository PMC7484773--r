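# seqmonitor

Tools for studying how the evidence in a two-arm, binary-outcome randomized
trial evolves as participants accrue — and for monitoring such a trial with
Bayesian stopping rules instead of repeated significance tests.

If an unadjusted test is recomputed at every interim look, the P value
"dances" around the 0.05 line: a trial can be statistically significant at
one responder and not at the next, the chance of *ever* crossing the line on
null data inflates far beyond 5%, and resampling more participants from the
trial's own data will eventually make any nonzero sample effect
"significant". The package makes all of this directly observable, and
implements the alternative: a Bayesian group sequential monitor in which a
skeptical normal prior on the log odds ratio is updated at every look and
the trial stops on prespecified posterior probabilities of success or
futility — criteria that can be evaluated as often as new data arrive.

## The model

At a look with 2×2 cells $a, b$ (intervention events/non-events) and $c, d$
(control events/non-events):

- **Effect**: $\widehat{OR} = ad/bc$, with
  $\mathrm{SE}(\log\widehat{OR}) = \sqrt{1/a + 1/b + 1/c + 1/d}$, Wald CI
  $\exp(\log\widehat{OR} \pm z_{0.975}\,\mathrm{SE})$ and the two-sided
  normal P value. Zero cells get the Haldane–Anscombe +0.5 correction so
  trajectories are defined from the second responder onward.
- **Posterior**: $\theta = \log OR$ with skeptical prior
  $\theta \sim N(0, 0.2^2)$. The default engine is the conjugate
  precision-weighted update of the prior with $(\log\widehat{OR},
  \mathrm{SE})$; an exact grid posterior over the two-binomial likelihood
  (uniform prior on the control event probability) serves as oracle and as a
  small-sample fallback.
- **Stopping rule**: success when $P(OR > 1 \mid \text{data}) > 0.95$;
  futility when $P(1/1.25 < OR < 1.25 \mid \text{data}) > 0.95$.

A seedable generator produces accrual-ordered synthetic trials (allocation,
control event probability, true OR, completely-at-random attrition, regime
drift), and `run_oc()` compares naive peeking with the Bayesian rules on
thousands of simulated trials with paired seeds.

## Worked example

```r
library(seqmonitor)

# a synthetic stand-in for a 535-participant smoking-cessation trial
# (true OR 1.6, 30% attrition; outcomes are simulated, not the real trial's)
trial <- synthetic_trial_preset("smoking_trial")$records

traj <- trajectory(trial)          # OR / CI / P at every responder
nrow(traj)                         # 378 looks
nrow(find_crossings(traj))         # 15 crossings of the .05 line
stop_at_first_crossing(traj)
#>     n       or   ci_low  ci_high          p significant corrected
#> 90 91 2.628205 1.004872 6.873971 0.04885304        TRUE     FALSE

odds_ratio(tabulate_look(trial, sum(trial$responded)))
#> OR 1.887 (95% CI 1.173-3.036; P=0.00886)

monitor(trial, start_n = 20)       # skeptical prior N(0, 0.2^2)
#> Bayesian sequential monitor (conjugate): 328 look(s)
#>   stopped for success at n = 347
```

Naive peeking would have stopped this trial at responder 91 on a lucky
OR of 2.6 whose interval barely clears 1. The skeptical monitor needs 347
responders before the posterior probability of a benefit exceeds 95% — the
prior absorbs the early noise, and the final estimate it stops on (median
OR 1.30) is far more modest than the peeked one.

The scripts in `analysis/` run the full workflow on the two bundled study
designs: `01_simulate.R` generates the trials, `02_trajectories.R` draws the
P-value line dance and its crossings, `03_extension.R` resamples 400 extra
responders to show significance arriving by sample size alone,
`04_monitor.R` runs the Bayesian monitor, and
`05_operating_characteristics.R` measures type-I inflation under peeking
(naive crossing rate ≈ 0.34 at 481 looks versus 0.046 at a single final
look in 1000 null trials, with the Bayesian false-success rate at 0.02).
Each step writes its tables, figures and a reproducibility manifest under
`results/`.

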