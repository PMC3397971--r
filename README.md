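# attencert

Selective attention improves how well people discriminate a noisy visual motion
signal — but does it change how *confident* they feel by the same amount? In
precue/postcue motion-discrimination experiments, observers judge the global
direction of a random-dot stimulus (a four-alternative forced choice, chance =
0.25) under valid (attended, 80% of trials) or invalid attention cues, and then
report their decision certainty either on a 0–3 numerical scale or by wagering
on their own choice. The empirical signature of interest is a *dissociation*:
the psychometric function of certainty shifts leftward with attention more than
the psychometric function of accuracy does.

`attencert` implements the complete analysis pipeline for this paradigm as a
tidyverse-native R package, together with a parametric synthetic observer so
every stage can be exercised, calibrated and stress-tested without human data:

- **Synthetic observer** (`observer_params()`, `simulate_experiment()`):
  accuracy follows psi(x) = 0.25 + (0.75 − λ) · L(x; α, β) with a
  lower (better) threshold α under valid cues; internal confidence follows its
  own logistic of coherence on the certainty-index scale [0.25, 1] with
  Gaussian trial-to-trial jitter, discretized into ratings 0–3 or low/high
  wagers. The confidence threshold shift with attention is configurable
  independently of the accuracy shift — the ground truth the pipeline must
  recover.
- **Task design** (`generate_schedule()`, `staircase_*()`): exact 80/20
  valid/invalid cue allocation, independent uniform motion directions (so ~25%
  of trials are congruent), and a PEST-style adaptive staircase for coherence
  (start 80%, initial step 20%, halve on reversal / double when moving away
  from the 62.5%-correct target, terminate below 0.02%).
- **Psychometrics** (`fit_pf()`, `threshold_at()`, `tlr()`,
  `mc_model_comparison()`): maximum-likelihood logistic fits of accuracy and
  certainty versus coherence (certainty via an equidistant pseudo-binomial
  recoding), analytic threshold inversion at the 0.625 criterion, and the
  transformed-likelihood-ratio model comparison — TLR = 2(ℓ_A + ℓ_B −
  ℓ_pooled) — referred to a parametric-bootstrap null with the 95% exceedance
  rule.
- **Group statistics** (`cell_means()`, `zstandardize()`, `delta_z()`,
  `paired_t()`, `modified_z_outliers()`, `rating_frequencies()`,
  `control_subsets()`): per-subject cell means with a ≥90-trial filter,
  z-standardization to a common mean 0 / SD 1 within subject × measure,
  attention deltas Δz = z(valid) − z(invalid), paired t-tests, MAD-based
  modified z-score outlier screening (|M| > 3.5), rating-frequency balance
  checks around each observer's certainty threshold, and the control-subset
  reruns (non-congruent only, coherence < 50%, correct/incorrect splits,
  overlapping coherences).
- **Pipeline** (`run_config()`, `run_experiment()`): one call orchestrating
  simulate → fit → compare → group statistics → control reruns, with derived
  seeds, provenance-stamped CSV/JSON outputs, and broom-style `tidy()` /
  `glance()` plus `autoplot()` methods on every result type.

## Worked example

```r
library(attencert)

cfg <- run_config(
  variant = "SN",        # spatial attention, numerical certainty ratings
  n_subjects = 6, n_trials = 600,
  n_sims = 500, lambda = 0, seed = 42
)
run <- run_experiment(cfg)
run
#> <attencert_run: SN>  6 subjects, 3600 trials, seed 42
#> comparisons:
#>   accuracy_valid_vs_invalid              TLR =    13.80  MC p = 0.0020 *
#>   certainty_valid_vs_invalid             TLR =   226.11  MC p = 0.0020 *
#>   accuracy_vs_certainty_valid            TLR =   192.78  MC p = 0.0020 *
#>   accuracy_vs_certainty_invalid          TLR =   126.53  MC p = 0.0020 *
#>   certainty_valid_vs_invalid_correct     TLR =   170.27  MC p = 0.0020 *
#>   certainty_valid_vs_invalid_incorrect   TLR =    47.16  MC p = 0.0020 *
#> delta-z paired tests:
#>   accuracy delta vs 0                    t =   2.24  p = 0.075  (n = 6)
#>   certainty delta vs 0                   t =   8.02  p = 0.00049  (n = 6)
#>   certainty vs accuracy delta            t =   3.39  p = 0.019  (n = 6)
```

Reading this output: every Monte-Carlo model comparison rejects its pooled
single-function model (`MC p = 0.002` is the add-one floor at 500 bootstrap
simulations) — attention shifts both psychometric functions, and accuracy and
certainty functions differ within each cue condition. The Δz paired tests show
the headline pattern the generator encodes: certainty rises with attention
(t = 8.02) more than accuracy does (certainty-vs-accuracy delta, p = 0.019,
positive mean), here with only 6 simulated subjects.

Certainty thresholds (coherence at certainty index 0.625) from the fitted
functions:

```r
threshold_at(run$fits$certainty_valid,   0.625)
#> [1] 35.20778
threshold_at(run$fits$certainty_invalid, 0.625)
#> [1] 53.65238
```

The valid-cue threshold is far lower: attended stimuli reach the same felt
certainty at much weaker motion signals. `autoplot(run$fits$certainty_valid)`,
`autoplot(run$comparisons$certainty_valid_vs_invalid)` and `autoplot(run)`
draw the fitted functions, the bootstrap null distribution, and the Δz bar
summary.

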