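#' Monetary reward for a session's accuracy
#'
#' Session reward is a linear map of mean block accuracy: 0 Euros at 50%
#' correct (chance) rising linearly to 10 Euros at 100% correct, clamped at
#' 0 below chance.
#'
#' @param block_accuracies block accuracies in percent (0--100).
#' @return reward in Euros for the session.
#' @examples
#' compute_reward(75)            # 5 Euros
#' compute_reward(c(70, 80, 90)) # mean 80% -> 6 Euros
#' @export
compute_reward <- function(block_accuracies) {
  if (!is.numeric(block_accuracies) || !length(block_accuracies) ||
      any(!is.finite(block_accuracies)) ||
      any(block_accuracies < 0 | block_accuracies > 100))
    stop_param("accuracies must be percentages in [0, 100]")
  acc <- mean(block_accuracies)
  max(0, (acc - 50) / 50 * 10)
}

#' Default pipeline configuration
#'
#' Nested configuration for a full synthetic-experiment run: the task
#' design, the observer model and generating model, pupil-trace generation,
#' preprocessing, epoching windows, and statistical parameters, plus a
#' single global seed from which every stage derives its own RNG stream.
#'
#' @param seed global seed.
#' @return nested named list (class `"run_config"`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = seed,
    design = list(n_subjects = 15, blocks_per_subject = 24,
                  trials_per_block = 25, p_hard = 2 / 3,
                  sample_rate_hz = 1000),
    sdt = list(sigma = 0.133, generating_model = "belief"),
    pupil = list(),
    preprocess = list(pad_s = 0.1, low_hz = 0.01, high_hz = 6, order = 3,
                      window_s = 6, resolution_s = 0.25,
                      analysis_rate_hz = 50),
    epochs = list(span_choice = c(-1, 6), span_feedback = c(-1, 6),
                  min_delay_s = 7.5),
    stats = list(n_perm = 1000, alpha_cluster = 0.05)
  ), class = "run_config")
}

.validate_config <- function(config) {
  ref <- default_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra))
    stop_param("unknown config section(s): ", paste(extra, collapse = ", "))
  for (sec in c("design", "sdt", "preprocess", "epochs", "stats")) {
    if (is.null(config[[sec]])) next
    ok <- switch(sec,
      design = names(formals(task_design)),
      sdt = c("sigma", "generating_model", "rt_base", "rt_slope",
              "rt_noise_sd", "me_jitter_prop"),
      preprocess = names(ref$preprocess),
      epochs = names(ref$epochs),
      stats = names(ref$stats))
    extra <- setdiff(names(config[[sec]]), ok)
    if (length(extra))
      stop_param("unknown key(s) in config$", sec, ": ",
                 paste(extra, collapse = ", "))
  }
  if (!is.null(config$pupil)) {
    extra <- setdiff(names(config$pupil), names(formals(pupil_gen_params)))
    if (length(extra))
      stop_param("unknown key(s) in config$pupil: ",
                 paste(extra, collapse = ", "))
  }
  invisible(config)
}

#' Read a pipeline configuration from JSON
#'
#' Unknown sections or keys are rejected; values override the defaults of
#' [default_config()].
#'
#' @param path path to a JSON file.
#' @return a `"run_config"` list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- unclass(default_config())
  .validate_config(cfg)
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(cfg[[nm]])) base[[nm]][[k]] <- cfg[[nm]][[k]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  structure(base, class = "run_config")
}

# Assemble clean epochs and scalar summaries for every block of a run.
.epoch_all_blocks <- function(recs, behavior, config) {
  pp <- config$preprocess
  ep <- config$epochs
  ch <- list(); fb_stim <- list(); fb_fb <- list()
  for (rec in recs) {
    clean <- preprocess_pupil(rec, pad_s = pp$pad_s, low_hz = pp$low_hz,
                              high_hz = pp$high_hz, order = pp$order,
                              window_s = pp$window_s,
                              resolution_s = pp$resolution_s,
                              analysis_rate_hz = pp$analysis_rate_hz)
    ec <- extract_epochs(clean, behavior, "choice", span_s = ep$span_choice)
    ch[[length(ch) + 1L]] <- baseline_correct(ec, clean, "stimulus")
    ef <- extract_epochs(clean, behavior, "feedback",
                         span_s = ep$span_feedback)
    fb_stim[[length(fb_stim) + 1L]] <- baseline_correct(ef, clean, "stimulus")
    fb_fb[[length(fb_fb) + 1L]] <- baseline_correct(ef, clean, "feedback")
  }
  list(choice = do.call(c, ch),
       feedback_stimbase = do.call(c, fb_stim),
       feedback_fbbase = do.call(c, fb_fb))
}

#' Run the full pipeline on a synthetic experiment
#'
#' Simulate -> preprocess -> epoch -> analyze. Generates a complete
#' synthetic experiment under the configured generating model, preprocesses
#' every block, extracts choice- and feedback-locked epochs, and runs the
#' two headline analyses: (1) the Difficulty x Accuracy interaction on the
#' pre-feedback (-0.5--0 s before feedback, stimulus baseline) and
#' post-feedback (3--6 s after feedback, pre-feedback baseline) window
#' scalars, restricted to long-delay trials, with repeated-measures ANOVA
#' and paired sign-flip permutation tests; (2) model--pupil correlations of
#' the belief-state and stimulus-state predictions (four-condition scheme,
#' per-subject internal noise fit from that subject's choices).
#' Deterministic given the config's global seed.
#'
#' @param config a `"run_config"` (see [default_config()], [read_config()]).
#' @return list with `behavior`, `scalars` (per-trial window summaries),
#'   `interaction` (pre/post: per-subject summaries, ANOVA, permutation p),
#'   `correlation` (per model and interval, plus belief-vs-stimulus
#'   comparisons), and a provenance `manifest`.
#' @export
run_all <- function(config = default_config()) {
  .validate_config(config)
  seed <- config$seed
  design <- do.call(task_design,
                    c(config$design, list(seed = derive_seed(seed, 1))))
  trials <- generate_design(design)
  sdt <- config$sdt
  behavior <- simulate_behavior(
    trials, design, sigma = sdt$sigma %||% 0.133,
    model = sdt$generating_model %||% "belief",
    rt_base = sdt$rt_base %||% 0.9, rt_slope = sdt$rt_slope %||% 0.6,
    rt_noise_sd = sdt$rt_noise_sd %||% 0.15,
    me_jitter_prop = sdt$me_jitter_prop %||% 0.25,
    seed = derive_seed(seed, 2))
  params <- do.call(pupil_gen_params, config$pupil %||% list())
  recs <- synthesize_pupil(behavior, design, params,
                           seed = derive_seed(seed, 3))
  eps <- .epoch_all_blocks(recs, behavior, config)

  pre_win <- window_spec("pre_feedback")
  sus_win <- window_spec("sustained")
  md <- config$epochs$min_delay_s

  # pre-feedback scalar: -0.5..0 s before feedback, stimulus baseline
  pre <- eps$feedback_stimbase
  pre_scalar <- data.frame(pre$meta,
                           value = window_mean(pre, pre_win))
  pre_scalar <- filter_long_delays(pre_scalar, md, "delay_feedback_s")
  # post-feedback scalar: 3..6 s after feedback, pre-feedback baseline
  post <- eps$feedback_fbbase
  post_scalar <- data.frame(post$meta,
                            value = window_mean(post, sus_win))
  post_scalar <- filter_long_delays(post_scalar, md, "iti_s")

  analyze_interval <- function(sc, perm_seed) {
    ca <- condition_average(sc$value, sc$difficulty, sc$correct, sc$subject)
    long <- stats::reshape(
      ca[, c("subject", "Easy.Correct", "Easy.Error", "Hard.Correct",
             "Hard.Error")],
      direction = "long", idvar = "subject",
      varying = c("Easy.Correct", "Easy.Error", "Hard.Correct", "Hard.Error"),
      v.names = "value", timevar = "cell",
      times = c("Easy.Correct", "Easy.Error", "Hard.Correct", "Hard.Error"))
    long$difficulty <- sub("\\..*", "", long$cell)
    long$accuracy <- sub(".*\\.", "", long$cell)
    an <- rm_anova_2x2(long[, c("subject", "difficulty", "accuracy", "value")])
    pt <- permutation_test_paired(ca$interaction, 0,
                                  n_perm = config$stats$n_perm * 10,
                                  seed = perm_seed)
    list(summary = ca, anova = an, interaction_mean = mean(ca$interaction),
         p_value = pt$p_value)
  }
  interaction <- list(
    pre = analyze_interval(pre_scalar, derive_seed(seed, 4)),
    post = analyze_interval(post_scalar, derive_seed(seed, 5))
  )

  # cluster-based permutation on the interaction time courses
  keep_rows <- function(e, keep) {
    e$data <- e$data[keep, , drop = FALSE]
    e$meta <- e$meta[keep, , drop = FALSE]
    e
  }
  cluster_of <- function(epochs, delay_field, perm_seed) {
    tryCatch({
      ep <- keep_rows(epochs, epochs$meta[[delay_field]] >= md)
      tc <- condition_timecourses(ep)
      cluster_permutation(tc$interaction, tc$time,
                          alpha_cluster = config$stats$alpha_cluster,
                          n_perm = config$stats$n_perm, seed = perm_seed)
    }, error = function(e) NULL)
  }
  clusters <- list(
    choice_locked = cluster_of(eps$choice, "delay_feedback_s",
                               derive_seed(seed, 8)),
    feedback_locked = cluster_of(eps$feedback_fbbase, "iti_s",
                                 derive_seed(seed, 9))
  )

  # control analysis: RT-corrected pre-feedback responses regressed on
  # absolute motion energy, separately per accuracy class
  evidence_control <- tryCatch({
    rtc <- residualize_rt(pre_scalar$value, pre_scalar$rt_s,
                          pre_scalar$subject)
    ev <- calibrate_evidence(pre_scalar$motion_energy, pre_scalar$mu)
    regress_on_evidence(rtc, abs(ev), pre_scalar$correct,
                        pre_scalar$subject,
                        n_perm = config$stats$n_perm * 10,
                        seed = derive_seed(seed, 10))
  }, error = function(e) NULL)

  # model-pupil correlations: per-subject sigma, conditional predictions
  sigma_hat <- vapply(sort(unique(behavior$subject)), function(s) {
    b <- behavior[behavior$subject == s, ]
    fit_internal_noise(b$mu, b$choice)$sigma_hat
  }, numeric(1))
  names(sigma_hat) <- sort(unique(behavior$subject))
  corr_for <- function(sc, variable, perm_seed) {
    preds <- lapply(c(belief = "belief", stimulus = "stimulus"), function(mdl) {
      vapply(seq_len(nrow(sc)), function(i) {
        sg <- sigma_hat[[as.character(sc$subject[i])]]
        predict_from_evidence(sc$mu[i], sc$correct[i], sigma = sg,
                              model = mdl)[[variable]]
      }, numeric(1))
    })
    res <- lapply(preds, function(p) {
      model_pupil_correlation(p, sc$value, sc$subject,
                              scheme = "four_condition",
                              difficulty = sc$difficulty,
                              accuracy = sc$correct,
                              n_perm = config$stats$n_perm * 10,
                              seed = perm_seed)
    })
    res$belief_vs_stimulus <- compare_model_correlations(
      res$belief, res$stimulus, n_perm = config$stats$n_perm * 10,
      seed = perm_seed)
    res
  }
  correlation <- list(
    pre = corr_for(pre_scalar, "uncertainty", derive_seed(seed, 6)),
    post = corr_for(post_scalar, "complement_prediction_error",
                    derive_seed(seed, 7))
  )

  manifest <- list(
    seed = seed,
    stage_seeds = vapply(1:7, function(k) derive_seed(seed, k), integer(1)),
    design = unclass(design),
    sdt = config$sdt, pupil = unclass(params),
    preprocess = config$preprocess, epochs = config$epochs,
    stats = config$stats,
    n_trials = nrow(behavior), n_blocks = length(recs),
    generating_model = behavior$generating_model[1]
  )
  structure(list(behavior = behavior, sigma_hat = sigma_hat,
                 scalars = list(pre = pre_scalar, post = post_scalar),
                 interaction = interaction, clusters = clusters,
                 evidence_control = evidence_control,
                 correlation = correlation, manifest = manifest),
            class = "pupil_run")
}

#' @export
print.pupil_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d trials, generating model '%s'\n",
              x$manifest$n_trials, x$manifest$generating_model))
  cat(sprintf("  pre-feedback interaction:  %+0.4f (permutation p = %.4g)\n",
              x$interaction$pre$interaction_mean, x$interaction$pre$p_value))
  cat(sprintf("  post-feedback interaction: %+0.4f (permutation p = %.4g)\n",
              x$interaction$post$interaction_mean, x$interaction$post$p_value))
  cat(sprintf("  model-pupil r (pre):  belief %.3f, stimulus %.3f (diff p = %.4g)\n",
              x$correlation$pre$belief$mean_r,
              x$correlation$pre$stimulus$mean_r,
              x$correlation$pre$belief_vs_stimulus$p_value))
  cat(sprintf("  model-pupil r (post): belief %.3f, stimulus %.3f (diff p = %.4g)\n",
              x$correlation$post$belief$mean_r,
              x$correlation$post$stimulus$mean_r,
              x$correlation$post$belief_vs_stimulus$p_value))
  for (lk in names(x$clusters)) {
    cl <- x$clusters[[lk]]
    if (is.null(cl)) next
    sig <- cl$clusters[cl$clusters$p_value < 0.05, , drop = FALSE]
    cat(sprintf("  %s interaction clusters (p < 0.05): %d\n",
                sub("_", "-", lk), nrow(sig)))
  }
  if (!is.null(x$evidence_control))
    cat(sprintf("  evidence-regression interaction (RT-corrected): %+0.3f (p = %.4g)\n",
                x$evidence_control$mean, x$evidence_control$p_value))
  invisible(x)
}
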