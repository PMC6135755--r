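# Shared fixtures, built in code at test time.

# Default evidence magnitudes yielding 70% / 85% accuracy at sigma = 0.133
MU_HARD <- qnorm(0.70) * 0.133
MU_EASY <- qnorm(0.85) * 0.133

# Minimal synthetic recording: known kernel convolved with an event train
# plus optional white noise. Returns the recording and the generating kernel.
make_conv_recording <- function(n_events = 50, fs = 100, noise_sd = 0,
                                gain = 25, seed = 1,
                                event_type = "blink_end") {
  params <- pupil_gen_params(noise_sd = noise_sd, drift_sd = 0,
                             blink_rate_hz = 0, gain_cue = gain)
  rec <- generate_irf_session(params, n_trials = n_events,
                              sample_rate_hz = fs, seed = seed)
  if (event_type != "cue") rec$events$type <- event_type
  kernel_t <- seq(0, 6, by = 1 / fs)
  list(rec = rec, kernel = gain * pupil_irf(kernel_t), kernel_t = kernel_t)
}

# Tiny complete experiment at a reduced sampling rate, for pipeline tests.
small_experiment <- function(n_subjects = 2, blocks = 2, fs = 100, seed = 5,
                             model = "belief") {
  design <- task_design(n_subjects = n_subjects,
                        blocks_per_subject = blocks,
                        sample_rate_hz = fs, seed = seed)
  trials <- generate_design(design)
  behavior <- simulate_behavior(trials, design, model = model,
                                seed = seed + 1)
  recs <- synthesize_pupil(behavior, design, seed = seed + 2)
  list(design = design, behavior = behavior, recs = recs)
}
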