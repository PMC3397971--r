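---
title: "Dissociating attention effects on choice accuracy and certainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating attention effects on choice accuracy and certainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attencert)
```

## The scientific problem

In cued motion-discrimination experiments an observer judges the global
direction of a random-dot stimulus — four alternatives, so chance performance
is 0.25 — after a precue directs attention to one of two stimuli (a location,
or a color-defined dot population). The cue is valid on 80% of trials. After
the direction choice the observer reports decision certainty, either on a
four-level numerical scale (0 "guessed" … 3 "sure") or by wagering a low or
high stake on their own choice. Two families of performance curves result:
accuracy versus motion coherence, and certainty versus motion coherence, each
under valid and invalid cueing.

The question this package's pipeline answers is whether attention moves the
*subjective* curve (certainty) more than the *objective* one (accuracy). Two
independent statistical routes address it:

1. **Model comparison on psychometric fits.** Are two conditions' curves the
   same function? Fit one logistic to the pooled data and separate logistics
   per condition, and refer the transformed likelihood ratio to a
   parametric-bootstrap null.
2. **Z-standardized deltas.** Standardize each subject's per-level cell means
   to a common scale, form Δz = z(valid) − z(invalid) per measure, and compare
   accuracy and certainty deltas in paired t-tests. This route is free of the
   numerical coding of the certainty categories: any equidistant coding gives
   identical z-values (affine invariance, tested).

## The certainty index

Raw reports are mapped to a certainty index on [0.25, 1] so that certainty and
accuracy share an axis: ratings 0/1/2/3 become 0.25/0.50/0.75/1.0, wagers
low/high become 0.25/1.0. The floor matches 4AFC chance ("I guessed"), the
ceiling perfect discrimination. `map_confidence()` implements exactly this
coding and nothing else.

## The generative observer

No observer model accompanies the experimental paradigm itself; the one in
this package is the package's own construction, built to encode the paradigm's
hypothesis as configurable ground truth so that recovery and calibration can
be tested.

- **Choice channel.** P(correct at coherence x) = γ + (1 − γ − λ)·L(x; α, β),
  with γ = 0.25 fixed, lapse λ (default 0.02 — empirical asymptotes rarely
  reach 1), logistic L, slope β per % coherence, and threshold α lower for
  valid than invalid cues. Errors are distributed uniformly over the three
  wrong directions (no error structure is implied by the task). At x = α with
  λ = 0 the probability is exactly 0.625, the conventional 4AFC threshold
  criterion.
- **Confidence channel.** Internal confidence c(x) = 0.25 + 0.75·L(x; α_c,
  β_c) + ε, with ε ~ N(0, σ_c) in index units. The attention shift of α_c may
  exceed that of α — that configurable gap is the dissociation under study. By
  default confidence depends on coherence and cue only, not on whether the
  specific choice was correct (`cert_correct_boost = 0`): certainty rises with
  attention in correct and incorrect trials alike, and the uncoupled model is
  the simplest one producing that pattern. A coupling term is available.
- **Discretization** is fixed and reproducible: c is computed in index units,
  rescaled to u = (c − 0.25)/0.75, clipped to [0, 1], then cut at
  `rating_cuts` (default 0.25/0.5/0.75) into ratings 0–3, or at `wager_cut`
  (default 0.5) into low/high.

Cohort defaults follow the emulated study: SN 13 subjects × 1000–1100 trials,
SW 11 × 1000–1100, FN 11 × 1100–1200, FW 11 × 900–1000; fixed coherence
levels {5, 20, 50, 100}% sampled equally, or staircase-controlled coherence.
Default cohort-mean parameters are α = 20%/30% (valid/invalid accuracy), β =
0.12, α_c = 25%/45% (a certainty shift twice the accuracy shift), β_c = 0.08,
σ_c = 0.15, with 12% relative between-subject threshold jitter — values in
the range typical for motion-coherence psychophysics, chosen once as the
package's simulated study conditions.

What the generator does *not* emulate: sequential dependencies (learning,
fatigue, streaks), reaction times, eye movements, criterion drift, and
subject-idiosyncratic rating styles. Passing tests therefore demonstrate that
the pipeline's statistics behave correctly for data with the assumed
structure, not that real observers have that structure.

## Trial scheduling and the adaptive staircase

`generate_schedule()` uses exact allocation by default — ⌊0.8·n⌋ valid cues in
shuffled order — so the 80% figure is an exact, testable property; a Bernoulli
mode exists. Both motion directions are independent uniform draws, making
~25% of trials congruent (both stimuli carry the same direction); the
`noncongruent_only` control subset removes them.

The staircase tracks the 62.5%-correct level. The historical description
specifies the start (80% coherence), initial step (20%), the halve-on-
convergence / double-on-divergence rule and the 0.02% termination bound, but
not the decision statistic. We implement the canonical PEST scheme: at the
current level keep counts (n, k) and step only when |k − 0.625·n| exceeds a
deviation bound W = 1 — down if performance is above target, up if below. A
direction reversal halves the step; after 3 consecutive same-direction steps
the step doubles, capped at the 20% starting step ("if possible"); when a
halving drives the step below 0.02% the run terminates and restarts fresh.
Whether the original used a per-level sequential count or a running
proportion, and the exact doubling cap, are not recorded; all constants are
exposed in `staircase_options()`. Coherence is clamped to [0.02, 100]% (no
bounds are stated historically; a staircase must not leave the stimulus
range). One staircase serves both cueing conditions by default, the simplest
reading of the shared-coherence design. Simulation shows terminal coherence
levels whose true P(correct) averages within ±5 percentage points of 62.5%
over 10 restarts.

## Psychometric fitting

`fit_pf()` maximizes the per-level binomial log-likelihood of
psi(x) = γ + (1 − γ − λ)·L(x; α, β) by bounded L-BFGS-B with analytic
gradients and a 5-start threshold grid (α ∈ [0.1, 200], β ∈ [10⁻³, 10], λ ∈
[0, 0.1] free by default or fixable; ties broken by log-likelihood then by
smaller slope). γ is fixed at 0.25 for both measures — 4AFC chance, and the
certainty-index floor. Certainty trials enter as pseudo-binomial counts: an
index v ∈ {0.25, 0.5, 0.75, 1} contributes k = 3(v − 0.25)/0.75 successes out
of 3 (wagers: 0 or 1 of 1), which is order- and mean-preserving because the
categories are equidistant by instruction; a single likelihood machinery then
serves both measures. Degenerate data (identical proportions everywhere) and
flat profiles (slope at its bound) are flagged, and `threshold_at()`
propagates them as an undefined (`NA`) threshold — as happens empirically in
hard unattended conditions where even 100% coherence never reaches a 0.625
certainty index. `threshold_at()` inverts psi analytically and returns `NA`
for criteria outside (γ, 1 − λ) or requiring coherence above 100%.

## Monte-Carlo model comparison

`tlr()` computes TLR = 2(ℓ_A + ℓ_B − ℓ_pooled) ≥ 0 (pooled model nested in
the separate one). `mc_model_comparison()` simulates `n_sims` dataset pairs
from the *pooled* fit at the observed per-level trial counts — the null
hypothesis of one shared function — refits both models to each pair, and
declares the conditions different when the observed TLR exceeds 95% of the
null TLRs (strictly above the ⌈0.95·n⌉-th order statistic). The p-value uses
the add-one estimator (1 + #{null ≥ observed})/(n_sims + 1), never exactly
zero. The reference analysis style used 10000 simulations; the package
default is 1000 with `n_sims` exposed, and calibration checks run at 500.
Bootstrap refits start from the generating parameters with a single optimizer
start — standard parametric-bootstrap practice that also keeps runtime
desk-scale — while observed-data fits always use the full multi-start
procedure. Calibration is verified by simulation: under a true null the rule
rejects at its nominal 5% within three binomial standard errors over 200
replicates.

Whether the original Palamedes-based analysis freed the lapse rate, and which
model its bootstrap simulated from, are not recorded; this package documents
its choices (λ policy shared across the three fits of a comparison; pooled-fit
parametric bootstrap).

## Group statistics

`cell_means()` aggregates trials into subject × measure × condition ×
coherence cells. The ≥90-trial inclusion filter is applied at *level*
granularity by default: a subject's coherence level is kept when it carries at
least 90 trials counted across both cue conditions. Under the paradigm's own
proportions (80/20 cue split, ~1000 trials, 4 levels) a per-condition-cell
reading of the filter would leave no invalid cell above 90 trials and empty
every downstream delta — level granularity is the only reading consistent
with the analyses the filter is meant to feed. The stricter per-cell variant
remains available (`filter_scope = "cell"`).

`zstandardize()` pools each subject's included cells of one measure — both
cue conditions together, the "common mean" that makes valid-minus-invalid
differences meaningful — and standardizes to mean 0, SD 1 (verified to
10⁻¹²). `delta_z()` pairs matched cells; positive Δz means improvement with
attention.

**Pairing unit for the certainty-vs-accuracy test.** Cells of one subject
share a z-pool and are therefore dependent; treating subject × level cells as
independent pairs makes the paired t-test anticonservative (measured ~10–16%
false-dissociation rate under equal generative shifts instead of the nominal
5%). The default therefore averages each subject's deltas per measure and
pairs subjects (`pairing = "subject"`, measured 5–9% across seed batches);
the per-cell variant is kept for sensitivity analyses. `paired_t()` itself is
the textbook statistic, cross-checked against `stats::t.test()`.

`modified_z_outliers()` implements the Iglewicz–Hoaglin modified z-score
M = 0.6745(x − median)/MAD with the standard |M| > 3.5 criterion; a zero MAD
(e.g. all-equal input) warns and excludes nothing. `control_subsets()`
provides the pure filters for the sensitivity reruns (non-congruent trials
only — retaining ~75%; strictly-below-50% coherence; correct/incorrect
splits; per-subject overlapping coherence levels for the matched-performance
design in which invalid cues receive on average higher coherences).
`run_experiment()` reruns the Δz statistics under each of these
automatically.

## Rating-frequency balance

If the four certainty categories are used uniformly and are equidistant, then
within a window of ±10 percentage points of coherence around an observer's
certainty threshold the lowest and highest ratings should be equally frequent,
as should the two middle ones. `rating_frequencies()` tabulates per-subject
frequencies in that window and runs the three group-level paired tests (0 vs
3, 1 vs 2, 0+1 vs 2+3), skipping (and counting) subjects whose threshold is
undefined.

A limitation found while validating this module: under the Gaussian-noise
discretized confidence generator, the expected certainty-index curve is
*steeper* than the γ-floored logistic family, and the precision-weighted ML
fit then overestimates the certainty threshold by several percentage points of
coherence. A window centered on such a biased threshold produces a spurious
imbalance of extreme ratings even for a perfectly symmetric confidence
distribution. `rating_frequencies()` therefore accepts externally supplied
thresholds (`thresholds =`), and the balance property is verified at the
generative point of symmetry; when thresholds are estimated from the same
fits, the balance tests should be interpreted with this bias in mind.

## Numerical and reproducibility choices

- Optimizer non-convergence from all starts is an error; in the bootstrap,
  isolated refit failures are tolerated up to 5% of simulations and reported,
  beyond that the comparison errors out.
- TLR is guaranteed ≥ −10⁻⁶ numerically; property-tested on random small
  datasets.
- Every stochastic stage of `run_experiment()` receives a seed derived from
  the master seed (kept below 2³¹); identical configurations reproduce
  byte-identical output files, which carry a provenance stamp (config hash and
  seed) in a comment header.
- Degenerate inputs (empty trial tables, single-level data, zero-spread
  z-pools, zero-variance differences, zero MAD) return flagged results or
  informative errors rather than silent numbers; the all-zero-differences
  paired test reports t = 0 with an undefined p.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at deliberately modest sizes,
chosen as a balance between statistical resolution and a quick, reproducible
desk run: parameter recovery at 10⁴ trials (±10% threshold tolerance), the
staircase at 10 restarts (±5 points on the tracked percent correct), bootstrap
calibration at 200 replicates × 500 simulations (3-binomial-SE band around
5%), and the end-to-end dissociation at 20 subjects × 1000 trials with a
100-replicate equal-shift calibration. Larger runs only tighten these bands.
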