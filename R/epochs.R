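#' Window specification for scalar pupil summaries
#'
#' Two canonical windows: the sustained window 3--6 s after the locking
#' event (where the impulse response has returned to baseline, so sustained
#' activity reflects cognitive modulation), and the pre-feedback window
#' -0.5--0 s relative to feedback. Edges are half-open: \[start, end).
#'
#' @param name `"sustained"` or `"pre_feedback"`, or any label.
#' @param start_s,end_s window edges in s relative to the locking event;
#'   defaults depend on `name`.
#' @return An object of class `"window_spec"`.
#' @export
window_spec <- function(name = c("sustained", "pre_feedback"),
                        start_s = NULL, end_s = NULL) {
  if (is.null(start_s) || is.null(end_s)) {
    name <- match.arg(name)
    if (name == "sustained") { start_s <- 3; end_s <- 6 }
    else { start_s <- -0.5; end_s <- 0 }
  }
  if (start_s >= end_s) stop_param("window start must be before end")
  structure(list(name = name, start_s = start_s, end_s = end_s),
            class = "window_spec")
}

#' Extract event-locked pupil epochs from a clean series
#'
#' Cuts one segment per trial around the locking event (choice or
#' feedback), joining trial metadata from the behavior table. Trials whose
#' epoch (or the event itself) falls outside the recording span, or that
#' lack the locking event (e.g. missed responses), are skipped and counted.
#'
#' @param rec a preprocessed `pupil_recording` (percent signal change).
#' @param behavior behavior table with columns `subject`, `block`, `trial`
#'   and metadata; matched on the recording's subject/block.
#' @param lock `"choice"` or `"feedback"`.
#' @param span_s epoch span relative to the event, s (default c(-1, 6)).
#' @return An object of class `"pupil_epochs"`: list with `data` (trials x
#'   time matrix), `time`, `lock`, `meta` (one row per kept trial, including
#'   `t_cue`/`t_feedback` event times), `baseline_corrected`, `n_dropped`.
#' @export
extract_epochs <- function(rec, behavior, lock = c("choice", "feedback"),
                           span_s = c(-1, 6)) {
  lock <- match.arg(lock)
  stopifnot(inherits(rec, "pupil_recording"))
  fs <- rec$rate
  n <- length(rec$samples)
  ev <- rec$events
  bb <- behavior[behavior$subject == rec$subject &
                   behavior$block == rec$block_id, , drop = FALSE]
  if (!nrow(bb)) stop_param("no behavior rows for this recording's block")
  lk <- ev[ev$type == lock, c("onset_s", "trial")]
  nt <- round((span_s[2] - span_s[1]) * fs) + 1L
  time <- span_s[1] + (seq_len(nt) - 1L) / fs
  rows <- list(); keep <- integer(0); dropped <- 0L
  for (i in seq_len(nrow(bb))) {
    tr <- bb$trial[i]
    t0 <- lk$onset_s[match(tr, lk$trial)]
    if (is.na(t0)) { dropped <- dropped + 1L; next }
    i0 <- round(t0 * fs) + 1L
    i1 <- i0 + round(span_s[1] * fs)
    i2 <- i1 + nt - 1L
    if (i1 < 1L || i2 > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- rec$samples[i1:i2]
    keep <- c(keep, i)
  }
  if (!length(rows)) stop_param("no epochs could be extracted")
  structure(list(
    data = do.call(rbind, rows),
    time = time,
    lock = lock,
    meta = bb[keep, , drop = FALSE],
    baseline_corrected = FALSE,
    n_dropped = dropped
  ), class = "pupil_epochs")
}

#' @export
print.pupil_epochs <- function(x, ...) {
  cat(sprintf("%d %s-locked epochs, %d samples (%.2f..%.2f s)%s; %d dropped\n",
              nrow(x$data), x$lock, ncol(x$data), min(x$time), max(x$time),
              if (x$baseline_corrected) ", baseline-corrected" else "",
              x$n_dropped))
  invisible(x)
}

#' Concatenate epochs across blocks or subjects
#'
#' @param ... `pupil_epochs` objects with identical lock and time axes.
#' @return a combined `pupil_epochs`.
#' @export
c.pupil_epochs <- function(...) {
  eps <- list(...)
  eps <- eps[!vapply(eps, is.null, logical(1))]
  e1 <- eps[[1]]
  for (e in eps[-1]) {
    if (e$lock != e1$lock || length(e$time) != length(e1$time) ||
        max(abs(e$time - e1$time)) > 1e-9)
      stop_param("epochs must share lock type and time axis")
    if (e$baseline_corrected != e1$baseline_corrected)
      stop_param("cannot mix baseline-corrected and uncorrected epochs")
  }
  e1$data <- do.call(rbind, lapply(eps, `[[`, "data"))
  e1$meta <- do.call(rbind, lapply(eps, `[[`, "meta"))
  e1$n_dropped <- sum(vapply(eps, `[[`, integer(1), "n_dropped"))
  e1
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial, the mean pupil value in the 0.5 s preceding a
#' reference event taken from the source series: the motion stimulus onset
#' (`reference = "stimulus"`, used for choice-locked epochs and for
#' pre-feedback scalars) or the feedback onset (`reference = "feedback"`,
#' which normalizes feedback-locked responses to the pre-feedback level so
#' they isolate the feedback-evoked component). Trials whose baseline
#' window leaves the recording are dropped.
#'
#' @param epochs a `pupil_epochs` from [extract_epochs()].
#' @param rec the same clean `pupil_recording` the epochs were cut from.
#' @param reference `"stimulus"` or `"feedback"`.
#' @param window_s baseline window length, s (default 0.5).
#' @return the corrected `pupil_epochs` (with `baseline_value` added to
#'   `meta`).
#' @export
baseline_correct <- function(epochs, rec,
                             reference = c("stimulus", "feedback"),
                             window_s = 0.5) {
  reference <- match.arg(reference)
  stopifnot(inherits(epochs, "pupil_epochs"), inherits(rec, "pupil_recording"))
  if (epochs$baseline_corrected) {
    # idempotent: the per-trial baseline has already been removed, so a
    # second application subtracts nothing
    return(epochs)
  }
  ref_type <- if (reference == "stimulus") "cue" else "feedback"
  ev <- rec$events
  refs <- ev[ev$type == ref_type, c("onset_s", "trial")]
  fs <- rec$rate
  n <- length(rec$samples)
  base <- rep(NA_real_, nrow(epochs$data))
  for (i in seq_len(nrow(epochs$data))) {
    tr <- epochs$meta$trial[i]
    t0 <- refs$onset_s[match(tr, refs$trial)]
    if (is.na(t0)) next
    i2 <- round(t0 * fs)            # sample just before the event
    i1 <- i2 - round(window_s * fs) + 1L
    if (i1 < 1L || i2 > n) next
    base[i] <- mean(rec$samples[i1:i2])
  }
  keep <- !is.na(base)
  dropped <- sum(!keep)
  epochs$data <- epochs$data[keep, , drop = FALSE] - base[keep]
  epochs$meta <- epochs$meta[keep, , drop = FALSE]
  epochs$meta$baseline_value <- base[keep]
  epochs$n_dropped <- epochs$n_dropped + dropped
  epochs$baseline_corrected <- TRUE
  epochs$baseline_reference <- reference
  epochs
}

#' Mean pupil response within a time window
#'
#' Arithmetic mean over the epoch samples with time in \[start, end)
#' (half-open edges).
#'
#' @param epochs a `pupil_epochs`.
#' @param spec a [window_spec()].
#' @return numeric vector, one scalar per epoch.
#' @export
window_mean <- function(epochs, spec = window_spec("sustained")) {
  stopifnot(inherits(epochs, "pupil_epochs"), inherits(spec, "window_spec"))
  sel <- epochs$time >= spec$start_s - 1e-9 & epochs$time < spec$end_s - 1e-9
  if (!any(sel)) stop_param("window [", spec$start_s, ", ", spec$end_s,
                            ") contains no samples")
  rowMeans(epochs$data[, sel, drop = FALSE])
}

#' Retain only trials with long delays before the next event
#'
#' Pupil responses on trials with short delays are contaminated by the next
#' event's response; the main analyses therefore keep only trials with the
#' three longest delay levels (7.5, 9.5, 11.5 s; 3/5 of trials under a
#' uniform 5-level design). Pre-feedback analyses filter on the
#' choice-to-feedback delay, post-feedback analyses on the inter-trial
#' interval.
#'
#' @param trials data.frame with the delay field.
#' @param min_delay_s retention threshold, s (default 7.5).
#' @param field delay column name (`"delay_feedback_s"` or `"iti_s"`).
#' @return the filtered data.frame.
#' @export
filter_long_delays <- function(trials, min_delay_s = 7.5,
                               field = "delay_feedback_s") {
  if (!field %in% names(trials))
    stop_param("delay field '", field, "' not present")
  out <- trials[trials[[field]] >= min_delay_s, , drop = FALSE]
  if (!nrow(out))
    warning("no trials remain after the long-delay filter", call. = FALSE)
  out
}

#' Per-subject 2x2 condition means and interaction
#'
#' Averages a per-trial scalar within each Difficulty x Accuracy cell per
#' subject and computes the interaction
#' `(Easy Error - Easy Correct) - (Hard Error - Hard Correct)`. Subjects
#' with an empty cell are excluded with a warning.
#'
#' @param values per-trial scalar (e.g. a window mean).
#' @param difficulty per-trial `"Easy"`/`"Hard"`.
#' @param accuracy per-trial 0/1 or `"Correct"`/`"Error"`.
#' @param subject per-trial subject id.
#' @return data.frame with one row per retained subject: cell means
#'   (`Easy.Correct`, `Easy.Error`, `Hard.Correct`, `Hard.Error`), cell
#'   counts, and `interaction`.
#' @export
condition_average <- function(values, difficulty, accuracy, subject) {
  stopifnot(length(values) == length(difficulty),
            length(values) == length(accuracy),
            length(values) == length(subject))
  if (is.numeric(accuracy)) accuracy <- ifelse(accuracy == 1, "Correct", "Error")
  cells <- c("Easy.Correct", "Easy.Error", "Hard.Correct", "Hard.Error")
  subs <- unique(subject)
  out <- list(); excluded <- character(0)
  for (s in subs) {
    sel <- subject == s
    key <- paste(difficulty[sel], accuracy[sel], sep = ".")
    ns <- vapply(cells, function(cl) sum(key == cl), integer(1))
    if (any(ns == 0L)) { excluded <- c(excluded, as.character(s)); next }
    mns <- vapply(cells, function(cl) mean(values[sel][key == cl]), numeric(1))
    row <- as.data.frame(as.list(mns))
    names(row) <- cells
    row$subject <- s
    row$interaction <- (mns[["Easy.Error"]] - mns[["Easy.Correct"]]) -
      (mns[["Hard.Error"]] - mns[["Hard.Correct"]])
    for (cl in cells) row[[paste0("n_", cl)]] <- ns[[cl]]
    out[[length(out) + 1L]] <- row
  }
  if (length(excluded))
    warning("subjects excluded for empty condition cells: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  if (!length(out)) stop_param("no subject has all four condition cells")
  res <- do.call(rbind, out)
  res[, c("subject", cells, "interaction", paste0("n_", cells))]
}

#' Per-subject 2x2 condition-mean time courses
#'
#' Like [condition_average()] but for full epochs: returns, per subject and
#' cell, the mean time course, plus the per-subject interaction time course.
#'
#' @param epochs a `pupil_epochs` whose `meta` has `difficulty`, `correct`,
#'   `subject`.
#' @return list with `subjects`, `time`, `cells` (list of subject x time
#'   matrices per cell), `interaction` (subject x time matrix).
#' @export
condition_timecourses <- function(epochs) {
  stopifnot(inherits(epochs, "pupil_epochs"))
  meta <- epochs$meta
  accuracy <- ifelse(meta$correct == 1, "Correct", "Error")
  key <- paste(meta$difficulty, accuracy, sep = ".")
  cells <- c("Easy.Correct", "Easy.Error", "Hard.Correct", "Hard.Error")
  subs <- sort(unique(meta$subject))
  mats <- lapply(cells, function(cl) {
    m <- matrix(NA_real_, length(subs), ncol(epochs$data))
    for (si in seq_along(subs)) {
      sel <- meta$subject == subs[si] & key == cl
      if (any(sel)) m[si, ] <- colMeans(epochs$data[sel, , drop = FALSE])
    }
    m
  })
  names(mats) <- cells
  keep <- Reduce(`&`, lapply(mats, function(m) !is.na(m[, 1])))
  mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
  inter <- (mats$Easy.Error - mats$Easy.Correct) -
    (mats$Hard.Error - mats$Hard.Correct)
  list(subjects = subs[keep], time = epochs$time, cells = mats,
       interaction = inter)
}
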