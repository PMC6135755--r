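#' Task design for a synthetic two-alternative forced-choice experiment
#'
#' Describes the random-dot motion discrimination task: blocks of 25 trials,
#' two coherence levels targeting 70% (Hard) and 85% (Easy) accuracy with
#' Hard trials on 2/3 of trials, feedback delays and inter-trial intervals
#' uniformly distributed over five levels from 3.5 to 11.5 s (steps of 2 s),
#' a 0.75 s stimulus and a response window closing 2.25 s after stimulus
#' offset. Default coherences are the evidence magnitudes at which an
#' unbiased observer with internal noise 0.133 reaches the target
#' accuracies: `qnorm(0.70) * 0.133` and `qnorm(0.85) * 0.133`.
#'
#' @param n_subjects number of synthetic subjects (default 15).
#' @param blocks_per_subject blocks per subject (default 24; 600 trials).
#' @param trials_per_block trials per block (default 25).
#' @param hard_coherence,easy_coherence coherence (evidence magnitude) of the
#'   Hard and Easy conditions, proportion units in (0, 0.5].
#' @param p_hard proportion of Hard trials (default 2/3).
#' @param delay_levels_s choice-to-feedback delay levels, seconds.
#' @param iti_levels_s feedback-to-next-trial interval levels, seconds.
#' @param baseline_range_s pre-stimulus fixation duration range, seconds.
#' @param stimulus_duration_s coherent-motion stimulus duration.
#' @param response_deadline_s response window after stimulus offset.
#' @param sample_rate_hz pupil sampling rate for trace synthesis.
#' @param seed RNG seed for the design draw.
#' @return An object of class `"task_design"`.
#' @export
task_design <- function(n_subjects = 15,
                        blocks_per_subject = 24,
                        trials_per_block = 25,
                        hard_coherence = stats::qnorm(0.70) * 0.133,
                        easy_coherence = stats::qnorm(0.85) * 0.133,
                        p_hard = 2 / 3,
                        delay_levels_s = seq(3.5, 11.5, by = 2),
                        iti_levels_s = seq(3.5, 11.5, by = 2),
                        baseline_range_s = c(0.5, 7),
                        stimulus_duration_s = 0.75,
                        response_deadline_s = 2.25,
                        sample_rate_hz = 1000,
                        seed = 1L) {
  d <- list(n_subjects = n_subjects, blocks_per_subject = blocks_per_subject,
            trials_per_block = trials_per_block,
            hard_coherence = hard_coherence, easy_coherence = easy_coherence,
            p_hard = p_hard, delay_levels_s = delay_levels_s,
            iti_levels_s = iti_levels_s, baseline_range_s = baseline_range_s,
            stimulus_duration_s = stimulus_duration_s,
            response_deadline_s = response_deadline_s,
            sample_rate_hz = sample_rate_hz, seed = seed)
  problems <- character(0)
  if (trials_per_block < 1) problems <- c(problems, "trials_per_block < 1")
  if (n_subjects < 1) problems <- c(problems, "n_subjects < 1")
  if (blocks_per_subject < 1) problems <- c(problems, "blocks_per_subject < 1")
  for (fld in c("hard_coherence", "easy_coherence")) {
    v <- d[[fld]]
    if (!is.numeric(v) || v <= 0 || v > 0.5) problems <- c(problems, paste(fld, "not in (0, 0.5]"))
  }
  if (d$hard_coherence >= d$easy_coherence)
    problems <- c(problems, "hard_coherence must be < easy_coherence")
  if (p_hard <= 0 || p_hard >= 1) problems <- c(problems, "p_hard not in (0, 1)")
  if (length(delay_levels_s) > 1 &&
      stats::var(diff(sort(delay_levels_s))) > 1e-12)
    problems <- c(problems, "delay_levels_s not uniformly spaced")
  if (sample_rate_hz <= 0) problems <- c(problems, "sample_rate_hz <= 0")
  if (length(problems))
    stop_param("invalid task design: ", paste(problems, collapse = "; "))
  structure(d, class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Task design\n")
  cat(sprintf("  %d subjects x %d blocks x %d trials\n", x$n_subjects,
              x$blocks_per_subject, x$trials_per_block))
  cat(sprintf("  coherence Hard %.4f (p = %.2f), Easy %.4f\n",
              x$hard_coherence, x$p_hard, x$easy_coherence))
  cat(sprintf("  delays/ITIs: %s s\n", paste(x$delay_levels_s, collapse = ", ")))
  invisible(x)
}

#' Draw the trial structure of a synthetic experiment
#'
#' Assigns per-trial difficulty (Hard with probability `p_hard`), stimulus
#' identity (+1/-1 equiprobable), pre-stimulus baseline duration,
#' choice-to-feedback delay and inter-trial interval (each uniform over the
#' design's five levels). Reproducible from the design seed.
#'
#' @param design a [task_design()].
#' @return data.frame with one row per trial: `subject`, `block`, `trial`,
#'   `difficulty`, `coherence`, `stimulus_identity`, `mu` (signed),
#'   `baseline_s`, `delay_feedback_s`, `iti_s`.
#' @export
generate_design <- function(design) {
  stopifnot(inherits(design, "task_design"))
  n <- design$n_subjects * design$blocks_per_subject * design$trials_per_block
  tab <- expand.grid(trial = seq_len(design$trials_per_block),
                     block = seq_len(design$blocks_per_subject),
                     subject = seq_len(design$n_subjects))
  tab <- tab[, c("subject", "block", "trial")]
  with_seed(design$seed, {
    hard <- stats::runif(n) < design$p_hard
    tab$difficulty <- ifelse(hard, "Hard", "Easy")
    tab$coherence <- ifelse(hard, design$hard_coherence, design$easy_coherence)
    tab$stimulus_identity <- sample(c(-1, 1), n, replace = TRUE)
    tab$mu <- tab$stimulus_identity * tab$coherence
    tab$baseline_s <- stats::runif(n, design$baseline_range_s[1],
                                   design$baseline_range_s[2])
    tab$delay_feedback_s <- sample(design$delay_levels_s, n, replace = TRUE)
    tab$iti_s <- sample(design$iti_levels_s, n, replace = TRUE)
  })
  rownames(tab) <- NULL
  tab
}

#' Simulate behavior on a drawn trial structure
#'
#' Draws the decision variable, choice and accuracy from an [sdt_model()],
#' generates reaction times that scale with decision uncertainty
#' (RT = base + slope x uncertainty + Gaussian noise, truncated to
#' (0.15 s, deadline\]), a signed motion-energy scalar (nominal mu plus
#' within-condition Gaussian jitter), and the ground-truth uncertainty and
#' prediction error of the generating model. Event onsets (cue, choice,
#' feedback) are laid out block-relative, with a 12 s baseline lead-in per
#' block.
#'
#' @param trial_table output of [generate_design()].
#' @param design the [task_design()] used to draw it.
#' @param sigma internal noise of the simulated observers.
#' @param model generating model for the ground-truth internal variables:
#'   `"belief"` (uncertainty from the trial's dv) or `"stimulus"`
#'   (uncertainty from |mu| only, identical for correct and error trials).
#' @param rt_base,rt_slope,rt_noise_sd reaction-time model parameters,
#'   seconds (slope per unit uncertainty).
#' @param me_jitter_prop SD of motion-energy jitter as a proportion of the
#'   trial's coherence.
#' @param seed RNG seed.
#' @return data.frame of behavior records: the trial table plus `dv`,
#'   `choice`, `correct`, `feedback`, `rt_s`, `motion_energy`,
#'   `confidence_belief`, `confidence_stimulus`, `gt_uncertainty`,
#'   `gt_prediction_error`, and block-relative onsets `t_cue`, `t_choice`,
#'   `t_feedback`, `t_trial_end`.
#' @export
simulate_behavior <- function(trial_table, design, sigma = 0.133,
                              model = c("belief", "stimulus"),
                              rt_base = 0.9, rt_slope = 0.6,
                              rt_noise_sd = 0.15, me_jitter_prop = 0.25,
                              seed = 2L) {
  model <- match.arg(model)
  stopifnot(inherits(design, "task_design"))
  n <- nrow(trial_table)
  tab <- trial_table
  deadline <- design$stimulus_duration_s + design$response_deadline_s
  with_seed(seed, {
    tab$dv <- stats::rnorm(n, tab$mu, sigma)
    tab$choice <- sign1(tab$dv)
    tab$correct <- as.integer(tab$choice == sign1(tab$mu))
    tab$feedback <- tab$correct
    tab$confidence_belief <- prob_correct(abs(tab$dv), sigma)
    tab$confidence_stimulus <- prob_correct(abs(tab$mu), sigma)
    conf_gen <- if (model == "belief") tab$confidence_belief else tab$confidence_stimulus
    tab$gt_uncertainty <- 1 - conf_gen
    tab$gt_prediction_error <- tab$feedback - conf_gen
    rt <- rt_base + rt_slope * tab$gt_uncertainty +
      stats::rnorm(n, 0, rt_noise_sd)
    tab$rt_s <- pmin(pmax(rt, 0.1501), deadline)
    tab$motion_energy <- tab$mu +
      stats::rnorm(n, 0, me_jitter_prop * tab$coherence)
  })
  tab$generating_model <- model
  # block-relative event times: 12 s lead-in, then per trial
  # baseline -> cue (stimulus onset), choice at cue + rt,
  # feedback at choice + delay, next trial baseline starts after the ITI
  ord <- order(tab$subject, tab$block, tab$trial)
  tab <- tab[ord, ]
  t_cue <- numeric(n); t_choice <- numeric(n); t_feedback <- numeric(n)
  t_end <- numeric(n)
  blk <- interaction(tab$subject, tab$block, drop = TRUE)
  for (b in levels(blk)) {
    idx <- which(blk == b)
    t <- 12
    for (i in idx) {
      t <- t + tab$baseline_s[i]
      t_cue[i] <- t
      t_choice[i] <- t + tab$rt_s[i]
      t_feedback[i] <- t_choice[i] + tab$delay_feedback_s[i]
      t_end[i] <- t_feedback[i] + tab$iti_s[i]
      t <- t_end[i]
    }
  }
  tab$t_cue <- t_cue; tab$t_choice <- t_choice
  tab$t_feedback <- t_feedback; tab$t_trial_end <- t_end
  rownames(tab) <- NULL
  tab
}

#' Pupil trace generation parameters
#'
#' The forward model for a block's pupil trace: a canonical pupil impulse
#' response kernel \eqn{h(t) \propto t^{n} e^{-n t / t_{max}}} (peak
#' normalized to 1), transient impulses at cue, choice and feedback,
#' a sustained boxcar from choice to feedback scaled by the trial's
#' ground-truth uncertainty, a sustained boxcar from feedback to trial end
#' scaled by 1 - prediction error, everything convolved with the kernel and
#' superimposed on a baseline pupil level with white measurement noise and
#' smooth slow drift. Poisson blinks gate the trace to missing and leave a
#' small artifact transient at blink offset. Units are arbitrary
#' (conversion to percent signal change is a preprocessing step).
#'
#' @param irf_shape_n IRF exponent (dimensionless; default 10.1).
#' @param irf_tmax_s IRF peak latency, s (default 0.93).
#' @param gain_cue,gain_choice,gain_feedback transient impulse amplitudes,
#'   arbitrary units.
#' @param sustained_gain_pre boxcar amplitude per unit uncertainty.
#' @param sustained_gain_post boxcar amplitude per unit (1 - prediction
#'   error).
#' @param noise_sd white measurement noise SD, arbitrary units.
#' @param drift_sd slow (~0.5 Hz knot spline) drift SD, arbitrary units.
#' @param blink_rate_hz Poisson blink rate.
#' @param blink_duration_s blink gap duration.
#' @param blink_gain artifact impulse amplitude at blink offset.
#' @param baseline_au baseline pupil level, arbitrary units.
#' @return An object of class `"pupil_gen_params"`.
#' @export
pupil_gen_params <- function(irf_shape_n = 10.1, irf_tmax_s = 0.93,
                             gain_cue = 30, gain_choice = 30,
                             gain_feedback = 30,
                             sustained_gain_pre = 60,
                             sustained_gain_post = 40,
                             noise_sd = 15, drift_sd = 10,
                             blink_rate_hz = 0.2, blink_duration_s = 0.15,
                             blink_gain = -40, baseline_au = 1000) {
  p <- list(irf_shape_n = irf_shape_n, irf_tmax_s = irf_tmax_s,
            gain_cue = gain_cue, gain_choice = gain_choice,
            gain_feedback = gain_feedback,
            sustained_gain_pre = sustained_gain_pre,
            sustained_gain_post = sustained_gain_post,
            noise_sd = noise_sd, drift_sd = drift_sd,
            blink_rate_hz = blink_rate_hz,
            blink_duration_s = blink_duration_s, blink_gain = blink_gain,
            baseline_au = baseline_au)
  if (p$irf_tmax_s <= 0) stop_param("irf_tmax_s must be > 0")
  if (p$noise_sd < 0 || p$drift_sd < 0) stop_param("noise SDs must be >= 0")
  if (any(!vapply(p, is.finite, logical(1))))
    stop_param("all pupil generation parameters must be finite")
  structure(p, class = "pupil_gen_params")
}

#' Canonical pupil impulse response kernel
#'
#' \eqn{h(t) = (t / t_{max})^{n} e^{n (1 - t/t_{max})}}, peak-normalized
#' to 1 at `tmax`.
#'
#' @param t time points, s.
#' @param n shape exponent.
#' @param tmax peak latency, s.
#' @return kernel values.
#' @export
pupil_irf <- function(t, n = 10.1, tmax = 0.93) {
  h <- ifelse(t < 0, 0, (t / tmax)^n * exp(n * (1 - t / tmax)))
  h[!is.finite(h)] <- 0
  h
}

.make_recording <- function(samples, rate, events, block_id, subject) {
  structure(list(samples = samples, rate = rate, start = 0,
                 events = events, block_id = block_id, subject = subject,
                 units = "au", provenance = character(0)),
            class = "pupil_recording")
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("Pupil recording: subject %s block %s, %d samples @ %g Hz (%.1f s), units %s\n",
              as.character(x$subject), as.character(x$block_id),
              length(x$samples), x$rate, length(x$samples) / x$rate, x$units))
  if (nrow(x$events)) {
    tb <- table(x$events$type)
    cat("  events:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# convolve input with kernel, same length as input (causal)
.conv_causal <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                       type = "open")
  y[seq_len(n)]
}

#' Synthesize continuous pupil recordings for each block
#'
#' Applies the forward model of [pupil_gen_params()] to the event times and
#' ground-truth internal variables of a behavior table, producing one
#' `pupil_recording` object per subject x block with an annotated
#' event table (cue, choice, feedback, blink_start, blink_end).
#'
#' @param behavior output of [simulate_behavior()].
#' @param design the [task_design()].
#' @param params a [pupil_gen_params()].
#' @param seed RNG seed for noise and blinks.
#' @return list of `pupil_recording` objects.
#' @export
synthesize_pupil <- function(behavior, design, params = pupil_gen_params(),
                             seed = 3L) {
  stopifnot(inherits(design, "task_design"), inherits(params, "pupil_gen_params"))
  fs <- design$sample_rate_hz
  kernel_t <- seq(0, 6, by = 1 / fs)
  kernel <- pupil_irf(kernel_t, params$irf_shape_n, params$irf_tmax_s)
  ksum <- sum(kernel)  # steady-state gain of a unit boxcar
  blocks <- unique(behavior[, c("subject", "block")])
  recs <- vector("list", nrow(blocks))
  for (bi in seq_len(nrow(blocks))) {
    sub <- blocks$subject[bi]; blk <- blocks$block[bi]
    tb <- behavior[behavior$subject == sub & behavior$block == blk, ]
    tb <- tb[order(tb$trial), ]
    if (any(diff(tb$t_cue) <= 0))
      stop_param("overlapping block boundaries: non-increasing event times")
    dur <- max(tb$t_trial_end) + 12
    nsamp <- ceiling(dur * fs)
    tt <- (seq_len(nsamp) - 1) / fs
    input <- numeric(nsamp)
    at <- function(t) pmin(pmax(round(t * fs) + 1, 1), nsamp)
    # transient impulses
    input[at(tb$t_cue)] <- input[at(tb$t_cue)] + params$gain_cue
    input[at(tb$t_choice)] <- input[at(tb$t_choice)] + params$gain_choice
    input[at(tb$t_feedback)] <- input[at(tb$t_feedback)] + params$gain_feedback
    # sustained boxcars: per-sample amplitude scaled so the steady-state
    # level after convolution equals gain x internal variable
    for (i in seq_len(nrow(tb))) {
      i1 <- at(tb$t_choice[i]); i2 <- at(tb$t_feedback[i])
      amp_pre <- params$sustained_gain_pre * tb$gt_uncertainty[i] / ksum
      input[i1:(i2 - 1)] <- input[i1:(i2 - 1)] + amp_pre
      i3 <- at(tb$t_trial_end[i])
      amp_post <- params$sustained_gain_post *
        (1 - tb$gt_prediction_error[i]) / ksum
      input[i2:(i3 - 1)] <- input[i2:(i3 - 1)] + amp_post
    }
    sub_seed <- derive_seed(seed, bi)
    rec <- with_seed(sub_seed, {
      # blinks: Poisson process; artifact impulse at blink offset shares the
      # IRF dynamics, and the gap itself is gated to missing afterwards
      ev_blinks <- NULL
      bs <- be <- numeric(0)
      if (params$blink_rate_hz > 0) {
        nb <- stats::rpois(1, params$blink_rate_hz * dur)
        if (nb > 0) {
          bs <- sort(stats::runif(nb, 1, dur - 2))
          be <- bs + params$blink_duration_s
          input[at(be)] <- input[at(be)] + params$blink_gain
          ev_blinks <- data.frame(
            onset_s = c(bs, be),
            type = rep(c("blink_start", "blink_end"), each = nb),
            trial = NA_integer_)
        }
      }
      trace <- params$baseline_au + .conv_causal(input, kernel)
      if (params$noise_sd > 0)
        trace <- trace + stats::rnorm(nsamp, 0, params$noise_sd)
      if (params$drift_sd > 0) {
        knots <- seq(0, dur + 2, by = 2)
        kv <- stats::rnorm(length(knots), 0, params$drift_sd)
        trace <- trace + stats::spline(knots, kv, xout = tt)$y
      }
      for (j in seq_along(bs)) trace[at(bs[j]):at(be[j])] <- NA_real_
      events <- rbind(
        data.frame(onset_s = tb$t_cue, type = "cue", trial = tb$trial),
        data.frame(onset_s = tb$t_choice, type = "choice", trial = tb$trial),
        data.frame(onset_s = tb$t_feedback, type = "feedback", trial = tb$trial),
        ev_blinks
      )
      events <- events[order(events$onset_s), ]
      rownames(events) <- NULL
      .make_recording(trace, fs, events, blk, sub)
    })
    recs[[bi]] <- rec
  }
  recs
}

#' Synthesize an impulse-response estimation session
#'
#' Emulates the auditory detection task used to measure the pupil impulse
#' response: brief salient cues at random intervals uniform on 2--6 s, each
#' evoking only a transient response, with measurement noise. Used to test
#' IRF deconvolution under event overlap.
#'
#' @param params a [pupil_gen_params()].
#' @param n_trials number of cues (default 25; one block).
#' @param sample_rate_hz sampling rate.
#' @param seed RNG seed.
#' @return a `pupil_recording` with `cue` events.
#' @export
generate_irf_session <- function(params = pupil_gen_params(), n_trials = 25,
                                 sample_rate_hz = 1000, seed = 4L) {
  if (n_trials < 1) stop_param("n_trials must be >= 1")
  fs <- sample_rate_hz
  with_seed(seed, {
    isi <- stats::runif(n_trials, 2, 6)
    onsets <- 5 + cumsum(isi)
    dur <- max(onsets) + 10
    nsamp <- ceiling(dur * fs)
    kernel <- pupil_irf(seq(0, 6, by = 1 / fs), params$irf_shape_n,
                        params$irf_tmax_s)
    input <- numeric(nsamp)
    idx <- round(onsets * fs) + 1
    input[idx] <- input[idx] + params$gain_cue
    trace <- params$baseline_au + .conv_causal(input, kernel)
    if (params$noise_sd > 0)
      trace <- trace + stats::rnorm(nsamp, 0, params$noise_sd)
    events <- data.frame(onset_s = onsets, type = "cue",
                         trial = seq_len(n_trials))
    .make_recording(trace, fs, events, block_id = "irf", subject = NA)
  })
}
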