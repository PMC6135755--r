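#' Pupil preprocessing
#'
#' The four canonical steps applied to each block's raw trace, in order:
#' (i) linear interpolation around blinks, (ii) zero-phase band-pass
#' filtering (third-order Butterworth, 0.01--6 Hz), (iii) removal of
#' responses to blink and saccade events by FIR deconvolution, and
#' (iv) conversion to percent signal change relative to the block mean.
#' Each step records itself in the recording's provenance and refuses to
#' run twice on the same series.
#'
#' @name preprocess
NULL

.check_step <- function(rec, step) {
  stopifnot(inherits(rec, "pupil_recording"))
  if (step %in% rec$provenance)
    stop_param("step '", step, "' already applied to this recording")
}

.add_step <- function(rec, step, ...) {
  pars <- list(...)
  lbl <- if (length(pars)) {
    paste0(step, "(", paste(names(pars), unlist(pars), sep = "=",
                            collapse = ", "), ")")
  } else step
  rec$provenance <- c(rec$provenance, step)
  attr(rec, "provenance_detail") <- c(attr(rec, "provenance_detail"), lbl)
  rec
}

#' Linearly interpolate pupil samples around blinks
#'
#' Samples from `pad_s` before each blink onset to `pad_s` after each blink
#' offset (plus any unflagged missing samples) are replaced by linear
#' interpolation between the nearest valid samples; overlapping windows are
#' merged. Blinks touching the recording edge are extended with the nearest
#' valid sample.
#'
#' @param rec a `pupil_recording`.
#' @param pad_s padding around each blink, s (default 0.1).
#' @return the recording with interpolated samples.
#' @export
interpolate_blinks <- function(rec, pad_s = 0.1) {
  .check_step(rec, "interpolate_blinks")
  if (pad_s < 0) stop_param("pad_s must be >= 0")
  x <- rec$samples
  n <- length(x)
  fs <- rec$rate
  bad <- is.na(x)
  ev <- rec$events
  starts <- ev$onset_s[ev$type == "blink_start"]
  ends <- ev$onset_s[ev$type == "blink_end"]
  if (length(starts) && length(ends)) {
    nb <- min(length(starts), length(ends))
    for (j in seq_len(nb)) {
      i1 <- max(1L, floor((starts[j] - pad_s) * fs) + 1L)
      i2 <- min(n, ceiling((ends[j] + pad_s) * fs) + 1L)
      if (i1 <= i2) bad[i1:i2] <- TRUE
    }
  }
  if (any(bad)) {
    good <- which(!bad)
    if (!length(good)) stop_param("no valid samples left to interpolate from")
    x[bad] <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
  }
  rec$samples <- x
  .add_step(rec, "interpolate_blinks", pad_s = pad_s,
            n_interpolated = sum(bad))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes the block mean, then applies a zero-phase (forward-backward)
#' third-order Butterworth high-pass at `low_hz` followed by a low-pass at
#' `high_hz`. The sequential high/low cascade is used because a directly
#' designed band-pass with a 0.01 Hz corner is numerically unstable at
#' typical pupil sampling rates.
#'
#' @param rec a `pupil_recording` (blinks interpolated; no missing values).
#' @param low_hz,high_hz passband edges, Hz (defaults 0.01 and 6).
#' @param order filter order (default 3).
#' @return the filtered recording (zero mean).
#' @export
bandpass <- function(rec, low_hz = 0.01, high_hz = 6, order = 3) {
  .check_step(rec, "bandpass")
  fs <- rec$rate
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop_param("need 0 < low_hz < high_hz < Nyquist (", fs / 2, " Hz)")
  x <- rec$samples
  if (anyNA(x)) stop_param("missing samples; run interpolate_blinks first")
  minlen <- 12 * (2 * order + 1)
  if (length(x) < minlen)
    stop_param("recording too short for filtering; need at least ",
               minlen, " samples (", signif(minlen / fs, 3), " s)")
  x <- x - mean(x)
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  rec$samples <- as.numeric(y)
  .add_step(rec, "bandpass", low_hz = low_hz, high_hz = high_hz, order = order)
}

# Sparse FIR (boxcar-bin) design matrix for event-related deconvolution.
# One column per (event type, lag bin); bin j of an event at time t0 covers
# samples with t - t0 in [j*res, (j+1)*res).
.fir_design <- function(onsets_list, n, fs, window_s, resolution_s) {
  nb <- floor(window_s / resolution_s)
  cols <- list(); rows <- list(); labels <- character(0)
  col0 <- 0L
  for (e in seq_along(onsets_list)) {
    onsets <- onsets_list[[e]]
    for (j in seq_len(nb)) {
      idx <- unlist(lapply(onsets, function(t0) {
        i1 <- floor((t0 + (j - 1) * resolution_s) * fs) + 1L
        i2 <- floor((t0 + j * resolution_s) * fs)
        if (i2 < i1 || i1 > n) return(integer(0))
        seq.int(max(i1, 1L), min(i2, n))
      }))
      rows[[length(rows) + 1L]] <- idx
      cols[[length(cols) + 1L]] <- rep.int(col0 + j, length(idx))
    }
    labels <- c(labels, rep(names(onsets_list)[e], nb))
    col0 <- col0 + nb
  }
  X <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = 1, dims = c(n, col0))
  list(X = X, labels = labels, n_bins = nb,
       bin_centers = (seq_len(nb) - 0.5) * resolution_s)
}

# Least-squares FIR deconvolution with an explicit intercept (the baseline
# level is estimated jointly, not pre-subtracted, so kernels are unbiased
# even when event windows tile the whole series). Returns per-type kernels
# and the fitted event-related signal (intercept excluded).
.fir_deconvolve <- function(y, onsets_list, fs, window_s, resolution_s) {
  n <- length(y)
  des <- .fir_design(onsets_list, n, fs, window_s, resolution_s)
  X <- cbind(Matrix::Matrix(1, n, 1, sparse = TRUE), des$X)
  XtX <- as.matrix(Matrix::crossprod(X))
  # guard against rank deficiency (too few events per type)
  if (rcond(XtX) < 1e-12) {
    counts <- vapply(onsets_list, length, integer(1))
    stop_param("deconvolution design is rank deficient; too few events ",
               "(counts: ", paste(names(counts), counts, sep = "=",
                                  collapse = ", "), ")")
  }
  beta <- solve(XtX, as.numeric(Matrix::crossprod(X, y)))
  fitted <- as.numeric(des$X %*% beta[-1])
  kernels <- split(beta[-1], des$labels)
  kernels <- kernels[names(onsets_list)]
  list(kernels = kernels, fitted = fitted, intercept = beta[1],
       time = des$bin_centers)
}

#' Remove blink and saccade responses by deconvolution
#'
#' Estimates the pupil response to each nuisance event type with a
#' finite-impulse-response (boxcar-bin) model fit by least squares over all
#' events jointly, then subtracts the fitted nuisance signal. Event types
#' with no events are omitted from the design.
#'
#' @param rec a filtered `pupil_recording`.
#' @param event_types nuisance types to remove; blink responses are
#'   time-locked to blink offsets (`blink_end` events).
#' @param window_s FIR window length, s (default 6).
#' @param resolution_s FIR bin width, s (default 0.25).
#' @return the residual recording; estimated kernels in
#'   `attr(, "nuisance_kernels")` (list of data.frames `time`, `kernel`).
#' @export
deconvolve_nuisance <- function(rec, event_types = c("blink", "saccade"),
                                window_s = 6, resolution_s = 0.25) {
  .check_step(rec, "deconvolve_nuisance")
  ev <- rec$events
  onsets_list <- list()
  for (ty in event_types) {
    key <- if (ty == "blink") "blink_end" else ty
    ons <- ev$onset_s[ev$type == key]
    if (length(ons)) onsets_list[[ty]] <- ons
  }
  if (!length(onsets_list)) {
    rec <- .add_step(rec, "deconvolve_nuisance", n_types = 0)
    attr(rec, "nuisance_kernels") <- list()
    return(rec)
  }
  res <- .fir_deconvolve(rec$samples, onsets_list, rec$rate, window_s,
                         resolution_s)
  rec$samples <- rec$samples - res$fitted - res$intercept
  rec <- .add_step(rec, "deconvolve_nuisance",
                   types = paste(names(onsets_list), collapse = "+"),
                   window_s = window_s, resolution_s = resolution_s)
  attr(rec, "nuisance_kernels") <- lapply(res$kernels, function(k) {
    data.frame(time = res$time, kernel = k)
  })
  rec
}

#' Convert a block to percent signal change
#'
#' `100 * (x - mean) / mean` with the mean taken over the whole block of the
#' *original* (pre-filtering) trace level; since filtering removes the mean,
#' the raw block mean must be supplied or carried on the recording. The
#' block mean is captured automatically before [bandpass()] demeans the
#' series.
#'
#' @param rec a `pupil_recording`.
#' @return the recording in percent-signal-change units (block mean of the
#'   psc series is ~0).
#' @export
to_percent_signal_change <- function(rec) {
  .check_step(rec, "to_percent_signal_change")
  baseline <- attr(rec, "block_mean")
  x <- rec$samples
  if (is.null(baseline)) baseline <- mean(x, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0)
    stop_param("non-positive block mean; pupil units misconfigured")
  if ("bandpass" %in% rec$provenance) {
    # filtering already removed the mean; scale to percent of raw level
    rec$samples <- 100 * x / baseline
  } else {
    rec$samples <- 100 * (x - mean(x)) / mean(x)
  }
  rec$units <- "psc"
  .add_step(rec, "to_percent_signal_change", block_mean = signif(baseline, 6))
}

#' Decimate a recording to an analysis sampling rate
#'
#' Anti-aliased decimation: zero-phase 4th-order Butterworth low-pass at 80%
#' of the target Nyquist, then subsampling by an integer factor. Event times
#' are unchanged.
#'
#' @param rec a `pupil_recording`.
#' @param target_hz new sampling rate; must divide the current rate.
#' @return the decimated recording.
#' @export
decimate_series <- function(rec, target_hz = 50) {
  stopifnot(inherits(rec, "pupil_recording"))
  q <- rec$rate / target_hz
  if (abs(q - round(q)) > 1e-9)
    stop_param("target rate must divide the current rate (", rec$rate, " Hz)")
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  lp <- signal::butter(4, 0.8 * (target_hz / 2) / (rec$rate / 2), type = "low")
  y <- signal::filtfilt(lp, rec$samples)
  rec$samples <- as.numeric(y[seq(1, length(y), by = q)])
  rec$rate <- target_hz
  .add_step(rec, "decimate", target_hz = target_hz)
}

#' Run the full preprocessing chain on one block
#'
#' Steps (i)--(iv) in order -- blink interpolation, band-pass, nuisance
#' deconvolution, percent signal change -- followed by decimation to the
#' analysis rate. The raw block mean is captured before filtering so that
#' percent signal change refers to the raw pupil level.
#'
#' @param rec a raw `pupil_recording`.
#' @param pad_s blink interpolation padding, s.
#' @param low_hz,high_hz,order band-pass parameters.
#' @param window_s,resolution_s nuisance FIR parameters.
#' @param analysis_rate_hz target rate for epoching/statistics (default 50;
#'   `NULL` to skip decimation).
#' @return a clean `pupil_recording` in percent-signal-change units.
#' @export
preprocess_pupil <- function(rec, pad_s = 0.1, low_hz = 0.01, high_hz = 6,
                             order = 3, window_s = 6, resolution_s = 0.25,
                             analysis_rate_hz = 50) {
  rec <- interpolate_blinks(rec, pad_s = pad_s)
  attr(rec, "block_mean") <- mean(rec$samples)
  rec <- bandpass(rec, low_hz = low_hz, high_hz = high_hz, order = order)
  rec <- deconvolve_nuisance(rec, window_s = window_s,
                             resolution_s = resolution_s)
  rec <- to_percent_signal_change(rec)
  if (!is.null(analysis_rate_hz) && analysis_rate_hz != rec$rate)
    rec <- decimate_series(rec, analysis_rate_hz)
  rec
}

#' Estimate the pupil impulse response function by deconvolution
#'
#' FIR deconvolution of the cue-locked response from a detection-task
#' recording, correcting for overlap between consecutive responses. Also
#' reports the peak latency and the time at which the kernel first returns
#' to baseline (first post-peak zero crossing), which motivates the 3--6 s
#' sustained analysis window.
#'
#' @param rec a `pupil_recording` (typically band-passed or raw with
#'   stable baseline).
#' @param window_s kernel window, s (default 6).
#' @param resolution_s FIR bin width, s (default 0.05 -- finer than the
#'   nuisance model so the peak latency is resolved).
#' @param cue_type event type to lock to (default `"cue"`).
#' @return An object of class `"pupil_irf"`: list with `time`, `kernel`,
#'   `peak_latency_s`, `return_to_baseline_s`, `n_events`.
#' @export
estimate_irf <- function(rec, window_s = 6, resolution_s = 0.05,
                         cue_type = "cue") {
  stopifnot(inherits(rec, "pupil_recording"))
  onsets <- rec$events$onset_s[rec$events$type == cue_type]
  if (!length(onsets)) stop_param("no '", cue_type, "' events in recording")
  if (length(onsets) < 25)
    warning("fewer than 25 cue events; IRF estimate may be noisy",
            call. = FALSE)
  y <- rec$samples
  if (anyNA(y)) stop_param("missing samples; interpolate blinks first")
  res <- .fir_deconvolve(y - mean(y), stats::setNames(list(onsets), cue_type),
                         rec$rate, window_s, resolution_s)
  k <- res$kernels[[cue_type]]
  tt <- res$time
  ipk <- which.max(k)
  post <- which(tt > tt[ipk] & k <= 0)
  structure(list(
    time = tt, kernel = k,
    peak_latency_s = tt[ipk],
    return_to_baseline_s = if (length(post)) tt[min(post)] else NA_real_,
    n_events = length(onsets)
  ), class = "pupil_irf")
}

#' @export
print.pupil_irf <- function(x, ...) {
  cat(sprintf("Pupil IRF estimate (%d events): peak %.2f s, back to baseline %s s\n",
              x$n_events, x$peak_latency_s,
              ifelse(is.na(x$return_to_baseline_s), "beyond window",
                     sprintf("%.2f", x$return_to_baseline_s))))
  invisible(x)
}

#' @export
plot.pupil_irf <- function(x, ...) {
  graphics::plot(x$time, x$kernel, type = "l", xlab = "time from cue (s)",
                 ylab = "pupil response (a.u.)", main = "Pupil impulse response",
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
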