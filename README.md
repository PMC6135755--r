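# pupilstate

Belief-state signals in task-evoked pupil responses.

`pupilstate` is an R package for testing whether sustained, task-evoked
pupil dilation tracks internal decision variables — decision uncertainty
before reward feedback and reward prediction error after it — or merely
the physical stimulus. It bundles three things:

1. **Two signal-detection observer models.** On each trial a decision
   variable is drawn as `dv ~ N(mu, sigma)` (`mu` = signed evidence
   strength, direction x motion coherence; `sigma` = internal noise, the
   reciprocal of the probit psychometric slope) and the choice is
   `sign(dv - c)` with unbiased bound `c = 0`. Confidence is
   `f(|dv - c|)` in the *belief-state* model and `f(|mu - c|)` in the
   *stimulus-state* model, where `f(x) = (1/2)[1 + erf(x/(sigma*sqrt(2)))]`
   is the probability the choice was correct. Uncertainty is
   `1 - confidence`; reward prediction error is `feedback - confidence`
   (feedback 0/1). The models are dissociated by the
   Difficulty x Accuracy interaction
   `(Easy Error - Easy Correct) - (Hard Error - Hard Correct)`:
   positive for belief-state uncertainty, negative for the belief-state
   complement of the prediction error, and exactly zero for
   stimulus-state uncertainty.
2. **A complete pupillometry pipeline**: blink interpolation, zero-phase
   0.01-6 Hz Butterworth band-pass, FIR deconvolution of blink/saccade
   responses, percent-signal-change conversion per block, impulse-response
   estimation, event-locked epoching with stimulus- or feedback-referenced
   baselines, sustained (3-6 s) and pre-feedback (-0.5-0 s) window
   summaries, long-delay trial selection, repeated-measures ANOVA,
   cluster-based permutation tests, sign-flip permutation tests, RT
   residualization, evidence-strength regressions, and model-pupil
   correlation analyses.
3. **A synthetic-experiment generator** with known ground truth (25-trial
   blocks, 70%/85% accuracy coherences in 2:1 proportion, 3.5-11.5 s
   delays, IRF-shaped transients plus sustained components scaled by the
   generating model's uncertainty and 1 - prediction error), so the whole
   pipeline is testable end to end without any recordings.

## Worked example

```r
library(pupilstate)

m <- sdt_model(sigma = 0.133)          # internal noise = 1 / probit slope 7.5
mu_hard <- qnorm(0.70) * 0.133         # coherence giving 70% accuracy
mu_easy <- qnorm(0.85) * 0.133         # coherence giving 85% accuracy
tr <- simulate(m, nsim = 20000, seed = 1,
               mu = c(-mu_easy, -mu_hard, mu_hard, mu_easy))
summarize_conditions(tr, "belief", "uncertainty",
                     easy_mus = mu_easy, hard_mus = mu_hard)
#> Condition summary (belief state model, uncertainty)
#>      Easy-Correct Easy-Error Hard-Correct Hard-Error
#> mean       0.1511     0.3207       0.2035     0.2884
#> n      33936.0000  6064.0000   27938.0000 12062.0000
#> Interaction (EE - EC) - (HE - HC): 0.0847
```

The belief-state uncertainty interaction is positive (+0.08): errors feel
much more uncertain than correct choices on easy trials, less so on hard
trials. The same call with `model = "stimulus"` prints an interaction of
exactly 0 — stimulus-state confidence cannot distinguish correct from
error trials.

A full synthetic experiment, from trial structure to group statistics:

```r
cfg <- default_config(seed = 101)
cfg$design$sample_rate_hz <- 100   # analysis content lies below 6 Hz
res <- run_all(cfg)
print(res)
#> Pipeline run: 9000 trials, generating model 'belief'
#>   pre-feedback interaction:  +0.6922 (permutation p = 0.0005999)
#>   post-feedback interaction: -0.8591 (permutation p = 0.0008999)
#>   model-pupil r (pre):  belief 0.873, stimulus 0.068 (diff p = 0.0003)
#>   model-pupil r (post): belief 0.978, stimulus 0.968 (diff p = 0.2114)
#>   choice-locked interaction clusters (p < 0.05): 2
#>   feedback-locked interaction clusters (p < 0.05): 1
#>   evidence-regression interaction (RT-corrected): +7.329 (p = 0.005)
```

The pipeline recovers the planted belief-state encoding: a positive
pre-feedback and negative post-feedback pupil interaction (in percent
signal change), significant clusters in the interaction time courses,
a positive evidence-strength regression interaction after RT correction,
and belief-state predictions that correlate with the measured pupil
responses better than stimulus-state predictions.

A thin command-line wrapper for shell use lives at
`inst/scripts/pupilpipe.R` (`simulate` and `analyze` subcommands).

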