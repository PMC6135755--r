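---
title: "Belief-state signals in task-evoked pupil responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-state signals in task-evoked pupil responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilstate)
```

# The scientific question

During a two-alternative forced-choice motion discrimination task, the pupil
dilates in a sustained fashion both while the observer awaits feedback and
after feedback is delivered. `pupilstate` implements the analysis machinery
for asking *which internal signal drives that sustained arousal*: a signal
computed from the observer's noisy internal belief about the stimulus, or
one computed from the physical stimulus alone.

# The two observer models

Both models share the same choice mechanism. On trial $i$ a decision
variable is drawn from a normal distribution around the signed evidence
strength $\mu$ (direction $\times$ motion coherence, in proportion-coherence
units on $[-0.5, 0.5]$):

$$dv_i \sim N(\mu_i, \sigma),$$

where $\sigma$ is the internal noise. The choice is the sign of
$dv_i - c$ with decision bound $c = 0$ (no bias), and a choice is correct
when it matches the sign of $\mu_i$. The models differ only in the quantity
entering the confidence computation:

* **Belief-state model**: confidence is $f(|dv_i - c|)$ — the observer's
  graded belief that the choice was correct, corrupted by the same noise
  that produced the choice.
* **Stimulus-state model**: confidence is $f(|\mu_i - c|)$ — a function of
  the physical stimulus only, identical on every trial of a coherence
  level.

Here $f(x) = \tfrac{1}{2}\left[1 + \mathrm{erf}(x/(\sigma\sqrt{2}))\right]$
maps a distance from the bound to the probability of being correct
(`prob_correct()`). Decision uncertainty is $1 - \text{confidence}$
(`uncertainty()`), and the reward prediction error is
$\text{feedback} - \text{confidence}$ with feedback coded 0/1
(`prediction_error()`). The post-feedback pupil is predicted to follow the
*complement* of the prediction error, $1 - PE$, by analogy with the
uncertainty scaling of pre-feedback responses.

The diagnostic statistic is the Difficulty $\times$ Accuracy interaction

$$(\text{Easy Error} - \text{Easy Correct}) -
  (\text{Hard Error} - \text{Hard Correct}),$$

computed by `summarize_conditions()` and `condition_average()`. The
belief-state model predicts a *positive* interaction for uncertainty
(pre-feedback) and a *negative* one for $1-PE$ (post-feedback); the
stimulus-state model predicts exactly zero for uncertainty, because its
confidence cannot differ between correct and error trials at a fixed
coherence.

```{r signs}
m <- sdt_model(sigma = 0.133)
mu_hard <- qnorm(0.70) * 0.133  # coherence giving 70% accuracy
mu_easy <- qnorm(0.85) * 0.133  # coherence giving 85% accuracy
tr <- simulate(m, nsim = 20000, seed = 1,
               mu = c(-mu_easy, -mu_hard, mu_hard, mu_easy))
summarize_conditions(tr, "belief", "uncertainty",
                     easy_mus = mu_easy, hard_mus = mu_hard)$interaction
summarize_conditions(tr, "stimulus", "uncertainty",
                     easy_mus = mu_easy, hard_mus = mu_hard)$interaction
```

## Parameters that matter

* `sigma` (internal noise, coherence units): default **0.133**, the
  reciprocal of a group-level probit psychometric slope of 7.5.
  `fit_internal_noise()` estimates it from choices by a maximum-likelihood
  probit fit of P(choice = up) on signed evidence, with a free intercept;
  only the slope enters $\hat\sigma = 1/\beta$. Fitting choice against
  signed evidence (rather than accuracy against |evidence|) yields the same
  slope under the unbiased model while tolerating sample bias.
* `bound` ($c$): default 0. `sign(0)` is defined as $+1$ so the choice rule
  is deterministic even at $dv = 0$, a probability-zero event for
  continuous $dv$.
* Evidence grid: $\mu \in [-0.5, 0.5]$ in steps of 0.01, 10,000 trials per
  level, for design-level model predictions.

## Evidence-conditioned predictions

`predict_from_evidence()` maps a single-trial evidence estimate (signed
motion energy calibrated to $\mu$ units by `calibrate_evidence()`, a linear
within-subject regression of nominal |coherence| on |motion energy|) plus
the trial's accuracy to expected uncertainty and $1-PE$. For the
belief-state model this requires the conditional mean of $f(|dv|)$ over the
$dv$ distribution truncated to the correct or error region. There is no
elementary closed form for that integral, so it is evaluated by adaptive
numerical quadrature (`stats::integrate`, relative tolerance $10^{-9}$) —
deterministic and independently checked against a large-sample simulation
oracle in the test suite. This is why error-trial uncertainty *increases*
with evidence strength while correct-trial uncertainty decreases, the
asymmetry that lets error trials dissociate the two models.

# The synthetic experiment generator

The generator (`task_design()`, `generate_design()`,
`simulate_behavior()`, `synthesize_pupil()`) emulates the task structure of
the experiment the analysis targets:

* 25-trial blocks; 15 subjects; 24 blocks per subject (≈600 trials) by
  default;
* two coherence levels targeting 70% (Hard) and 85% (Easy) accuracy at
  $\sigma = 0.133$ (defaults $\Phi^{-1}(0.70)\sigma \approx 0.070$ and
  $\Phi^{-1}(0.85)\sigma \approx 0.138$), Hard on 2/3 of trials;
* choice-to-feedback delays and inter-trial intervals uniform over
  $\{3.5, 5.5, 7.5, 9.5, 11.5\}$ s; pre-stimulus baseline 0.5–7 s; 0.75 s
  stimulus; response window closing 2.25 s after stimulus offset; 12 s
  baseline at block start and end;
* reaction times scale with the generating model's uncertainty:
  $RT = 0.9 + 0.6\,u + \varepsilon$, $\varepsilon \sim N(0, 0.15^2)$ s,
  truncated to $(0.15, 3]$ s. The base/slope/noise values are a modelling
  choice that reproduces the observed Easy ≈ 1.13 s vs Hard ≈ 1.22 s
  ordering qualitatively;
* per-trial signed motion energy $= \mu + N(0, (0.25\,\text{coherence})^2)$;
  the jitter magnitude is a design choice (the within-condition
  variability of real stimulus sequences is not published).

Pupil traces are generated by a linear time-invariant forward model: a
canonical impulse response kernel
$h(t) \propto (t/t_{max})^{n} e^{n(1 - t/t_{max})}$ with $n = 10.1$,
$t_{max} = 0.93$ s (the classic pupil IRF parameterization; the empirical
IRF has no published functional form), transient impulses at cue, choice
and feedback, a sustained boxcar from choice to feedback scaled by the
trial's uncertainty, and a boxcar from feedback to trial end scaled by
$1-PE$, all convolved with the kernel, on a baseline of 1000 a.u. with
white measurement noise (SD 15 a.u.), smooth slow drift (SD 10 a.u.), and
Poisson blinks (0.2 Hz, 150 ms gaps set to missing, with an IRF-shaped
artifact at blink offset) to exercise interpolation and nuisance
deconvolution. Transient gains of 30 a.u. and sustained gains of 60 (pre)
and 40 (post) a.u. per unit of the internal variable produce responses of
a few percent signal change, the magnitude typical of task-evoked pupil
dilation.

What the generator deliberately does **not** emulate: luminance transients
from the feedback color change, gaze-position foreshortening, saccades
(the nuisance design simply omits absent event types), non-stationary
arousal drift correlated with task variables, and missed-response trials
(the pipeline tolerates and drops trials lacking a choice event). Passing
the end-to-end tests therefore shows that the pipeline recovers a known
ground truth embedded in realistic-looking data, not that real data are
this clean.

# Preprocessing

`preprocess_pupil()` applies, per block, in enforced order (each step
records itself in a provenance trail and refuses to run twice):

1. **Blink interpolation** (`interpolate_blinks()`): linear interpolation
   from 0.1 s before blink onset to 0.1 s after blink offset, merged
   windows, edges extended with the nearest valid sample.
2. **Band-pass** (`bandpass()`): third-order Butterworth, 0.01–6 Hz,
   zero-phase (forward–backward). Zero-phase filtering is chosen because
   phase delay would shift epoch timing. A directly designed band-pass
   with a 0.01 Hz corner is numerically unstable at pupil sampling rates
   (we measured a gain of 5.2 at 3 Hz for the pole-zero form), so the
   filter is implemented as block demeaning followed by a zero-phase
   high-pass then low-pass cascade (measured gain 0.985 at 3 Hz, <0.001 at
   20 Hz).
3. **Nuisance deconvolution** (`deconvolve_nuisance()`): FIR (boxcar-bin)
   responses to blink offsets and saccade onsets, 6 s window at 0.25 s
   resolution, estimated jointly by sparse least squares and subtracted.
4. **Percent signal change** (`to_percent_signal_change()`):
   $100 (x - \bar{x})/\bar{x}$ with respect to the raw block mean
   (captured before filtering removes it).

After preprocessing, series are decimated to a 50 Hz analysis rate
(anti-aliased; all retained content lies below 6 Hz), which keeps the
cluster-based permutation tests fast without losing signal.

`estimate_irf()` estimates the impulse response from a separate detection
task session (cues at uniform 2–6 s intervals) by the same FIR machinery at
0.05 s resolution, correcting for overlap between consecutive responses;
its return-to-baseline time motivates treating 3–6 s after an event as a
window of purely sustained, cognitively driven activity.

# Epoching and window summaries

Epochs are cut at −1…6 s around the reported choice and around feedback
(`extract_epochs()`). Baselines (`baseline_correct()`) follow the logic of
the analysis: choice-locked epochs and pre-feedback scalars subtract the
mean of the 0.5 s before *stimulus onset*; feedback-locked epochs subtract
the 0.5 s before *feedback*, so post-feedback responses isolate the
feedback-evoked component. Scalar summaries (`window_mean()`) use half-open
windows $[start, end)$: the sustained window 3–6 s and the pre-feedback
window −0.5–0 s. The main analyses keep only trials with delays ≥ 7.5 s
before the next event (`filter_long_delays()`): the choice-to-feedback
delay for pre-feedback measures, the inter-trial interval for post-feedback
measures — 3/5 of trials under the uniform 5-level design.

The "sustained" window is applied on the choice-locked axis and the
pre-feedback window on the feedback-locked axis (with stimulus baseline);
this pairing follows the respective figure conventions of the analyses the
package reproduces, since the sustained pre-feedback ANOVA's axis is
otherwise ambiguous.

# Inference

* `cluster_permutation()`: paired t per time point, cluster-forming
  threshold at two-tailed $p < 0.05$ (a conventional choice; the method's
  original description leaves it free), cluster mass = summed t, null by
  sign-flipping whole subjects (default 1000 permutations), add-one
  corrected p. Family-wise error under an exchangeable null is verified by
  simulation in the test suite.
* `rm_anova_2x2()`: repeated-measures ANOVA via `stats::aov` with
  subject-level error strata; with 2-level factors each F equals the
  squared paired t on the corresponding contrast, which the tests check
  numerically.
* `permutation_test_paired()`: sign-flip test of the mean difference,
  exact (full $2^n$ enumeration) when feasible, Monte-Carlo with add-one
  correction otherwise.
* `residualize_rt()`: within-subject least-squares removal of RT from
  pupil measures, means re-added.
* `regress_on_evidence()`: within-subject slopes of (RT-corrected) pupil
  on absolute motion energy, separately for error and correct trials;
  interaction = slope difference; group inference by sign-flip
  permutation.
* `model_pupil_correlation()`: per-subject Pearson r between model
  predictions and pupil scalars under three schemes (2×2 cell means;
  six equal-count bins within subject, error trials only; single-trial),
  group-tested on Fisher-z values by sign-flip permutation, with paired
  model comparisons via `compare_model_correlations()`. Equal-count
  binning uses within-subject quantile ranks with ties broken by stable
  trial order, so bin counts differ by at most one. The single-trial
  variant is computed per subject and then group-tested (the pooling
  convention is an interpretation; trial-level pooling across subjects
  would conflate within- and between-subject variance).
* No correction is applied across the pre/post windows; each window is
  reported separately, matching the reporting convention of the analyses
  this package mirrors.

# Problem sizes and determinism

Every random stage accepts a seed, and the pipeline driver `run_all()`
derives per-stage sub-seeds from one global seed, so a full run is
bit-reproducible. The test suite exercises the complete pipeline at 15
subjects × 24 blocks (≈600 trials per subject, the target experiment's
scale) with traces generated at 100 Hz and analyzed at 50 Hz; generating
at 1000 Hz is supported but adds nothing scientifically, since all
analyzed content lies below 6 Hz. Model-level checks use 10,000–50,000
trials per evidence level; the family-wise-error simulation uses 500
null replications of 15 subjects.

# Known limitations

* The forward model is linear and stationary; real pupil dynamics show
  saturation and baseline-dependent gain.
* The belief-state conditional predictions assume the calibrated evidence
  scale is exact; miscalibration compresses the predicted effects.
* The RM-ANOVA assumes complete 2×2 cells; subjects missing a cell (rare
  Easy-Error trials in short runs) are excluded from that contrast rather
  than imputed.
* `condition_average()` weights trials equally within a cell; no shrinkage
  is applied across subjects.
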