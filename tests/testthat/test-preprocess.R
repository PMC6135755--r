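# Preprocessing: blink interpolation, band-pass, nuisance deconvolution,
# percent signal change, IRF estimation.

make_rec <- function(x, fs = 100, events = NULL) {
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), type = character(0),
                         trial = integer(0))
  structure(list(samples = x, rate = fs, start = 0, events = events,
                 block_id = 1, subject = 1, units = "au",
                 provenance = character(0)),
            class = "pupil_recording")
}

blink_events <- function(starts, ends) {
  data.frame(onset_s = c(starts, ends),
             type = rep(c("blink_start", "blink_end"),
                        c(length(starts), length(ends))),
             trial = NA_integer_)
}

test_that("blink interpolation restores linear segments exactly", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  # no blinks: identity
  rec <- make_rec(sin(t), fs)
  expect_equal(interpolate_blinks(rec)$samples, rec$samples)
  # constant signal with a gap stays constant
  x <- rep(5, length(t))
  x[301:320] <- NA
  rec <- make_rec(x, fs, blink_events(3, 3.2))
  expect_equal(interpolate_blinks(rec)$samples, rep(5, length(t)))
  # interior gap on a ramp: exact ramp restored (linearity)
  ramp <- 2 * t + 1
  xr <- ramp; xr[501:540] <- NA
  rec <- make_rec(xr, fs, blink_events(5, 5.4))
  expect_equal(interpolate_blinks(rec)$samples, ramp, tolerance = 1e-12)
  # blink at the recording edge: extended with nearest valid sample
  xe <- ramp; xe[1:20] <- NA
  rec <- make_rec(xe, fs, blink_events(0, 0.2))
  out <- interpolate_blinks(rec)$samples
  expect_false(anyNA(out))
  expect_error(interpolate_blinks(make_rec(x, fs), pad_s = -1), "pad_s")
})

test_that("band-pass has the specified frequency response", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  mid <- seq(2000, length(t) - 2000)
  gain_at <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- bandpass(make_rec(x, fs))$samples
    sd(y[mid]) / sd(x[mid])
  }
  # DC: constant input maps to zero everywhere
  expect_equal(bandpass(make_rec(rep(7, length(t)), fs))$samples,
               rep(0, length(t)))
  expect_equal(gain_at(3), 1, tolerance = 0.05)    # passband
  expect_lt(gain_at(20), 0.1)                      # stopband
  expect_error(bandpass(make_rec(rnorm(10), fs)), "too short")
  expect_error(bandpass(make_rec(rnorm(1000), fs), low_hz = 10, high_hz = 2),
               "Nyquist")
})

test_that("preprocessing steps are linear and refuse to run twice", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  a <- sin(2 * pi * 0.5 * t)
  b <- 0.3 * sin(2 * pi * 2 * t + 1)
  fa <- bandpass(make_rec(a, fs))$samples
  fb <- bandpass(make_rec(b, fs))$samples
  fab <- bandpass(make_rec(a + b, fs))$samples
  expect_equal(fab, fa + fb, tolerance = 1e-6)
  rec <- bandpass(make_rec(a, fs))
  expect_error(bandpass(rec), "already applied")
  expect_identical(rec$provenance, "bandpass")
})

test_that("nuisance deconvolution recovers and removes a known kernel", {
  fix <- make_conv_recording(n_events = 100, fs = 100, noise_sd = 3,
                             seed = 21, event_type = "blink_end")
  rec <- fix$rec
  out <- deconvolve_nuisance(rec, event_types = "blink",
                             window_s = 6, resolution_s = 0.25)
  ker <- attr(out, "nuisance_kernels")$blink
  # recovered kernel tracks the truth (bin-averaged)
  truth <- approx(fix$kernel_t, fix$kernel, xout = ker$time)$y
  expect_gt(cor(ker$kernel, truth), 0.95)
  # construction with a kernel in the FIR span: residuals reach the noise
  # floor exactly, and the bin estimates equal the generating staircase
  fs <- 100; res_s <- 0.25; nb <- 24
  k_true <- 20 * pupil_irf((seq_len(nb) - 0.5) * res_s)
  set.seed(22)
  onsets <- cumsum(runif(80, 2, 6))
  n <- ceiling((max(onsets) + 8) * fs)
  x <- numeric(n)
  for (t0 in onsets) {
    for (j in seq_len(nb)) {
      i1 <- floor((t0 + (j - 1) * res_s) * fs) + 1
      i2 <- min(floor((t0 + j * res_s) * fs), n)
      x[i1:i2] <- x[i1:i2] + k_true[j]
    }
  }
  noise <- rnorm(n, 0, 3)
  rec2 <- make_rec(x + noise, fs,
                   data.frame(onset_s = onsets, type = "blink_end",
                              trial = NA))
  out2 <- deconvolve_nuisance(rec2, event_types = "blink",
                              window_s = 6, resolution_s = res_s)
  expect_lte(var(out2$samples), var(noise) * 1.05)
  ker2 <- attr(out2, "nuisance_kernels")$blink
  expect_equal(ker2$kernel, k_true, tolerance = 0.1)
  # zero events: identity
  rec0 <- make_rec(rnorm(2000), 100)
  out0 <- deconvolve_nuisance(rec0)
  expect_identical(out0$samples, rec0$samples)
  # too few events for the FIR window: rank-deficient design
  rec1 <- make_rec(rnorm(500), 100,
                   data.frame(onset_s = 1, type = "blink_end", trial = NA))
  expect_error(deconvolve_nuisance(rec1, window_s = 20, resolution_s = 0.1),
               "rank deficient")
})

test_that("percent signal change is anchored to the block mean", {
  x <- rep(500, 1000)
  rec <- make_rec(x, 100)
  out <- to_percent_signal_change(rec)
  expect_equal(out$samples, rep(0, 1000))
  expect_identical(out$units, "psc")
  # one sample 2% above the mean maps to ~2.0
  x2 <- rep(500, 1000); x2[100] <- 500 * 1.02
  out2 <- to_percent_signal_change(make_rec(x2, 100))
  expect_equal(out2$samples[100], 2.0, tolerance = 0.01)
  expect_equal(mean(out2$samples), 0, tolerance = 1e-12)
  expect_error(to_percent_signal_change(make_rec(rep(-5, 100), 100)),
               "non-positive")
})

test_that("the full chain enforces step order in provenance", {
  fix <- small_experiment(n_subjects = 1, blocks = 1, seed = 31)
  clean <- preprocess_pupil(fix$recs[[1]])
  expect_identical(clean$provenance,
                   c("interpolate_blinks", "bandpass", "deconvolve_nuisance",
                     "to_percent_signal_change", "decimate"))
  expect_equal(clean$rate, 50)
  expect_false(anyNA(clean$samples))
  expect_equal(mean(clean$samples), 0, tolerance = 0.3)
  expect_error(to_percent_signal_change(clean), "already applied")
})

test_that("IRF deconvolution recovers the generating kernel under overlap", {
  params <- pupil_gen_params(noise_sd = 5, drift_sd = 0, blink_rate_hz = 0)
  rec <- generate_irf_session(params, n_trials = 75, sample_rate_hz = 100,
                              seed = 41)
  irf <- estimate_irf(rec, window_s = 6, resolution_s = 0.05)
  expect_equal(irf$peak_latency_s, 0.93, tolerance = 0.11)
  truth <- params$gain_cue *
    pupil_irf(irf$time, params$irf_shape_n, params$irf_tmax_s)
  expect_gt(cor(irf$kernel, truth), 0.95)
  # noiseless events: recovery limited only by the FIR bin quantization
  p0 <- pupil_gen_params(noise_sd = 0, drift_sd = 0, blink_rate_hz = 0)
  rec0 <- generate_irf_session(p0, n_trials = 30, sample_rate_hz = 100,
                               seed = 42)
  irf0 <- estimate_irf(rec0, window_s = 6, resolution_s = 0.05)
  fine <- seq(0, 6, by = 0.005)
  kf <- p0$gain_cue * pupil_irf(fine, p0$irf_shape_n, p0$irf_tmax_s)
  bin_avg <- tapply(kf, pmin(floor(fine / 0.05), length(irf0$kernel) - 1),
                    mean)
  expect_gt(cor(irf0$kernel, as.numeric(bin_avg)), 0.999)
  expect_error(estimate_irf(make_rec(rnorm(100), 100)), "no 'cue' events")
})

test_that("decimation preserves low-frequency content", {
  fs <- 200
  t <- seq(0, 30, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  rec <- make_rec(x, fs)
  dec <- decimate_series(rec, 50)
  expect_equal(dec$rate, 50)
  expect_equal(length(dec$samples), ceiling(length(x) / 4))
  mid <- seq(200, length(dec$samples) - 200)
  expect_equal(sd(dec$samples[mid]), sd(x) , tolerance = 0.02)
  expect_error(decimate_series(make_rec(x, fs), 60), "divide")
})
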