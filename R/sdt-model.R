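#' Signal detection theory model of choice, confidence and prediction error
#'
#' Constructs a static observer model for a two-alternative forced choice
#' task. On each trial a decision variable \eqn{dv} is drawn from
#' \eqn{N(\mu, \sigma)}, where \eqn{\mu} is the signed evidence strength
#' (direction times motion coherence, in proportion-coherence units) and
#' \eqn{\sigma} is the internal noise. The choice is the sign of
#' \eqn{dv - c}, where \eqn{c} is the decision bound (0 = unbiased).
#'
#' Two read-outs of decision confidence are carried side by side:
#' \describe{
#'   \item{belief state}{confidence is \eqn{f(|dv - c|)} -- the observer's
#'     graded internal belief that the choice was correct, corrupted by the
#'     same noise that drives the choice.}
#'   \item{stimulus state}{confidence is \eqn{f(|\mu - c|)} -- a function of
#'     the physical stimulus only, identical across trials of the same
#'     coherence.}
#' }
#' where \eqn{f} maps a distance to a probability of being correct via the
#' normal CDF (see [prob_correct()]). Decision uncertainty is
#' \eqn{1 - confidence}, and the reward prediction error is
#' \eqn{feedback - confidence} with feedback coded 0/1.
#'
#' @param sigma internal noise, the standard deviation of the decision
#'   variable distribution, in coherence units. The default 0.133 is the
#'   reciprocal of a group probit slope of 7.5.
#' @param bound decision bound \eqn{c} in coherence units; 0 means no choice
#'   bias.
#' @return An object of class `"sdt_model"`.
#' @seealso [simulate.sdt_model()], [fit_internal_noise()],
#'   [summarize_conditions()], [predict_from_evidence()]
#' @examples
#' m <- sdt_model()
#' trials <- simulate(m, mu = c(-0.07, 0.07), nsim = 500, seed = 1)
#' mean(trials$correct)
#' @export
sdt_model <- function(sigma = 0.133, bound = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_param("'sigma' must be a single positive finite number")
  if (!is.numeric(bound) || length(bound) != 1L || !is.finite(bound))
    stop_param("'bound' must be a single finite number")
  structure(list(sigma = sigma, bound = bound), class = "sdt_model")
}

#' @export
print.sdt_model <- function(x, ...) {
  cat("Signal detection observer model\n")
  cat(sprintf("  internal noise sigma: %.4g (probit slope 1/sigma = %.4g)\n",
              x$sigma, 1 / x$sigma))
  cat(sprintf("  decision bound c:     %.4g%s\n", x$bound,
              if (x$bound == 0) " (unbiased)" else ""))
  invisible(x)
}

#' @export
coef.sdt_model <- function(object, ...) {
  c(sigma = object$sigma, bound = object$bound)
}

#' Probability of a correct choice given a distance from the bound
#'
#' The link between a distance \eqn{x = |dv - c|} (or \eqn{|\mu - c|}) and
#' confidence: \eqn{f(x) = \frac{1}{2}[1 + erf(x / (\sigma\sqrt{2}))]},
#' i.e. the standard normal CDF evaluated at \eqn{x/\sigma}.
#'
#' @param x non-negative distance(s) from the decision bound, coherence units.
#' @param sigma internal noise (> 0).
#' @return Probabilities in \[0.5, 1); strictly increasing in `x`.
#' @examples
#' prob_correct(0.133, 0.133)  # distance of one noise SD: pnorm(1)
#' @export
prob_correct <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_param("'sigma' must be a single positive number")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop_param("'x' must be non-negative and finite")
  stats::pnorm(x / sigma)
}

#' Decision uncertainty: the complement of confidence
#'
#' @param confidence probabilities in \[0, 1\].
#' @return `1 - confidence`.
#' @export
uncertainty <- function(confidence) {
  if (!is.numeric(confidence) || any(!is.finite(confidence)) ||
      any(confidence < 0) || any(confidence > 1))
    stop_param("'confidence' must lie in [0, 1]")
  1 - confidence
}

#' Reward prediction error
#'
#' The difference between the experienced outcome and the expected outcome:
#' `feedback - confidence`, with feedback coded 0 (error) or 1 (correct).
#' The predicted post-feedback pupil quantity is its complement,
#' `1 - prediction_error`.
#'
#' @param feedback 0/1 vector of reward feedback.
#' @param confidence probabilities in \[0, 1\].
#' @return `feedback - confidence`, in (-1, 1).
#' @export
prediction_error <- function(feedback, confidence) {
  if (!is.numeric(feedback) || any(!feedback %in% c(0, 1)))
    stop_param("'feedback' must be binary (0/1)")
  if (!is.numeric(confidence) || any(!is.finite(confidence)) ||
      any(confidence < 0) || any(confidence > 1))
    stop_param("'confidence' must lie in [0, 1]")
  feedback - confidence
}

#' Simulate trials from the observer model
#'
#' For each evidence level in `mu`, draws `nsim` decision variables from
#' \eqn{N(\mu, \sigma)}, forms the choice as the sign of \eqn{dv - c}
#' (sign(0) = +1), scores accuracy against the sign of \eqn{\mu}, and
#' computes both confidence read-outs per trial.
#'
#' @param object an [sdt_model()].
#' @param nsim trials per evidence level (default 10000).
#' @param seed optional RNG seed; the caller's RNG state is untouched.
#' @param mu signed evidence strengths in \[-0.5, 0.5\]; defaults to the
#'   full grid -0.5 to 0.5 in steps of 0.01.
#' @param ... unused.
#' @return A data.frame with one row per trial and columns `mu`, `dv`,
#'   `choice` (+1/-1), `correct`, `feedback` (= correct), `confidence_belief`,
#'   `confidence_stimulus`, `uncertainty` (belief-state), `prediction_error`
#'   (belief-state).
#' @export
simulate.sdt_model <- function(object, nsim = 10000, seed = NULL,
                               mu = seq(-0.5, 0.5, by = 0.01), ...) {
  if (length(mu) == 0L) stop_param("'mu' must contain at least one evidence level")
  if (any(!is.finite(mu)) || any(abs(mu) > 0.5))
    stop_param("'mu' values must be finite and in [-0.5, 0.5]")
  if (!is.numeric(nsim) || length(nsim) != 1L || nsim < 1)
    stop_param("'nsim' must be a positive integer")
  nsim <- as.integer(nsim)
  sigma <- object$sigma
  cb <- object$bound
  mus <- rep(mu, each = nsim)
  dv <- with_seed(seed, stats::rnorm(length(mus), mean = mus, sd = sigma))
  choice <- sign1(dv - cb)
  correct <- as.integer(choice == sign1(mus))
  conf_b <- prob_correct(abs(dv - cb), sigma)
  conf_s <- prob_correct(abs(mus - cb), sigma)
  data.frame(
    mu = mus,
    dv = dv,
    choice = choice,
    correct = correct,
    feedback = correct,
    confidence_belief = conf_b,
    confidence_stimulus = conf_s,
    uncertainty = 1 - conf_b,
    prediction_error = correct - conf_b
  )
}

#' Condition summary: 2x2 cell means and the diagnostic interaction
#'
#' Collapses simulated (or behavioral) trials into the 2x2
#' Difficulty (Easy/Hard) x Accuracy (Correct/Error) design, averaging a
#' model variable per cell, and computes the interaction term
#' `(Easy Error - Easy Correct) - (Hard Error - Hard Correct)` that
#' dissociates the belief-state from the stimulus-state read-out.
#' Coherence levels are collapsed across the sign of \eqn{\mu}.
#'
#' @param trials data.frame from [simulate.sdt_model()] (needs `mu`,
#'   `correct`, `feedback`, `confidence_belief`, `confidence_stimulus`).
#' @param model `"belief"` or `"stimulus"`: which confidence read-out.
#' @param variable `"uncertainty"` (1 - confidence) or
#'   `"complement_prediction_error"` (1 - (feedback - confidence)).
#' @param easy_mus,hard_mus absolute evidence magnitudes defining the Easy
#'   and Hard conditions; every trial's |mu| must belong to exactly one.
#' @param subject_id optional identifier carried into the result.
#' @return An object of class `"condition_summary"`: list with
#'   `cell_means`, `cell_ns` (named Easy-Correct, Easy-Error, Hard-Correct,
#'   Hard-Error), `interaction`, `variable_name`, `model`, `subject_id`.
#' @export
summarize_conditions <- function(trials,
                                 model = c("belief", "stimulus"),
                                 variable = c("uncertainty",
                                              "complement_prediction_error"),
                                 easy_mus, hard_mus, subject_id = NA) {
  model <- match.arg(model)
  variable <- match.arg(variable)
  stopifnot(is.data.frame(trials))
  amu <- abs(trials$mu)
  tol <- 1e-9
  in_set <- function(x, set) vapply(x, function(v) any(abs(v - set) < tol), logical(1))
  easy <- in_set(amu, abs(easy_mus))
  hard <- in_set(amu, abs(hard_mus))
  if (any(easy & hard))
    stop_param("some |mu| values belong to both easy_mus and hard_mus")
  if (any(!easy & !hard))
    stop_param("some |mu| values belong to neither easy_mus nor hard_mus")
  conf <- if (model == "belief") trials$confidence_belief else trials$confidence_stimulus
  value <- switch(variable,
    uncertainty = 1 - conf,
    complement_prediction_error = 1 - (trials$feedback - conf)
  )
  difficulty <- ifelse(easy, "Easy", "Hard")
  accuracy <- ifelse(trials$correct == 1, "Correct", "Error")
  cells <- c("Easy-Correct", "Easy-Error", "Hard-Correct", "Hard-Error")
  key <- paste(difficulty, accuracy, sep = "-")
  ns <- vapply(cells, function(cl) sum(key == cl), integer(1))
  if (any(ns == 0L))
    stop_param("empty condition cell(s): ",
               paste(cells[ns == 0L], collapse = ", "),
               " -- simulate more trials")
  means <- vapply(cells, function(cl) mean(value[key == cl]), numeric(1))
  interaction <- (means[["Easy-Error"]] - means[["Easy-Correct"]]) -
    (means[["Hard-Error"]] - means[["Hard-Correct"]])
  structure(list(
    subject_id = subject_id,
    variable_name = variable,
    model = model,
    cell_means = means,
    cell_ns = ns,
    interaction = interaction
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition summary (%s state model, %s)\n", x$model, x$variable_name))
  tab <- rbind(mean = x$cell_means, n = x$cell_ns)
  print(round(tab, 4))
  cat(sprintf("Interaction (EE - EC) - (HE - HC): %.4f\n", x$interaction))
  invisible(x)
}

#' Estimate internal noise from choices by probit psychometric fit
#'
#' Fits a probit psychometric function, P(choice = +1) as a function of the
#' signed evidence strength, by maximum likelihood (binomial GLM with probit
#' link, free intercept). The internal noise estimate is the reciprocal of
#' the slope, \eqn{\hat\sigma = 1/\beta}.
#'
#' @param signed_mu signed evidence strength per trial.
#' @param choice choices coded +1/-1.
#' @return An object of class `"psychometric_fit"`: list with `beta` (probit
#'   slope per unit coherence), `bias` (intercept), `sigma_hat = 1/beta`,
#'   `n_trials`.
#' @examples
#' m <- sdt_model(sigma = 0.133)
#' tr <- simulate(m, nsim = 2000, seed = 2, mu = seq(-0.3, 0.3, by = 0.05))
#' fit <- fit_internal_noise(tr$mu, tr$choice)
#' fit$sigma_hat
#' @export
fit_internal_noise <- function(signed_mu, choice) {
  if (length(signed_mu) != length(choice))
    stop_param("'signed_mu' and 'choice' must have equal length")
  if (any(!choice %in% c(-1, 1)))
    stop_param("'choice' must be coded +1/-1")
  if (length(unique(abs(signed_mu))) < 2L)
    stop_param("need at least 2 distinct |mu| levels")
  y <- as.integer(choice == 1)
  if (all(y == 1L) || all(y == 0L))
    stop_param("degenerate data: all choices identical; probit fit impossible")
  # aggregate to binomial counts per evidence level (equivalent ML, faster)
  lev <- sort(unique(signed_mu))
  k <- vapply(lev, function(m) sum(y[signed_mu == m]), numeric(1))
  n <- vapply(lev, function(m) sum(signed_mu == m), numeric(1))
  # perfect separation: slope diverges, no ML estimate
  if (all(k == 0 | k == n))
    stop_param("probit fit failed: data are (near-)separable, slope diverges")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(k, n - k) ~ lev, family = stats::binomial(link = "probit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit)[2])
  if (sep_warn && abs(beta) > 50)
    stop_param("probit fit failed: data are (near-)separable, slope diverges")
  if (!is.finite(beta) || beta <= 0)
    stop_param("probit fit failed: non-positive or non-finite slope")
  structure(list(
    beta = beta,
    bias = unname(stats::coef(fit)[1]),
    sigma_hat = 1 / beta,
    n_trials = sum(n)
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Probit psychometric fit\n")
  cat(sprintf("  slope beta:  %.4g per unit coherence\n", x$beta))
  cat(sprintf("  bias:        %.4g\n", x$bias))
  cat(sprintf("  sigma = 1/beta: %.4g  (n = %d trials)\n", x$sigma_hat,
              as.integer(x$n_trials)))
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(beta = object$beta, bias = object$bias, sigma_hat = object$sigma_hat)
}

# Conditional expectation of belief-state confidence given accuracy, by
# numerical integration over the dv distribution truncated to the correct or
# error region. m = |mu| > bound assumed positive-direction w.l.o.g.
.belief_conf_conditional <- function(m, sigma, correct, bound = 0) {
  # dv ~ N(m, sigma); correct region dv >= bound, error region dv < bound
  p_region <- if (correct) stats::pnorm((m - bound) / sigma)
              else stats::pnorm((bound - m) / sigma)
  if (p_region < 1e-12) return(NA_real_)
  integrand <- function(v) {
    stats::pnorm(abs(v - bound) / sigma) * stats::dnorm(v, mean = m, sd = sigma)
  }
  lims <- if (correct) c(bound, m + 10 * sigma) else c(m - 10 * sigma, bound)
  val <- stats::integrate(integrand, lims[1], lims[2], rel.tol = 1e-9)$value
  val / p_region
}

#' Per-trial model predictions from single-trial evidence
#'
#' Maps a single-trial estimate of delivered sensory evidence (signed motion
#' energy, calibrated to \eqn{\mu} units) plus the trial's accuracy to the
#' expected pre-feedback uncertainty and post-feedback complement of the
#' prediction error under either observer model. For the belief-state model
#' the expectation is over the decision-variable distribution truncated to
#' the correct/error region (deterministic numerical integration); for the
#' stimulus-state model confidence depends on |evidence| only.
#'
#' @param evidence signed per-trial evidence in calibrated \eqn{\mu} units
#'   (\[-0.5, 0.5\]; values outside are clipped with a warning).
#' @param accuracy 0/1 per trial.
#' @param sigma internal noise.
#' @param model `"belief"` or `"stimulus"`.
#' @param bound decision bound (default 0).
#' @return data.frame with columns `uncertainty` and
#'   `complement_prediction_error`, one row per trial.
#' @seealso [calibrate_evidence()]
#' @export
predict_from_evidence <- function(evidence, accuracy, sigma,
                                  model = c("belief", "stimulus"), bound = 0) {
  model <- match.arg(model)
  if (length(evidence) != length(accuracy))
    stop_param("'evidence' and 'accuracy' must have equal length")
  if (any(!accuracy %in% c(0, 1)))
    stop_param("'accuracy' must be binary (0/1)")
  if (any(abs(evidence) > 0.5)) {
    warning("evidence outside calibrated range [-0.5, 0.5]; clipping",
            call. = FALSE)
    evidence <- pmin(pmax(evidence, -0.5), 0.5)
  }
  m <- abs(evidence)
  if (model == "stimulus") {
    conf <- prob_correct(abs(m - bound), sigma)
  } else {
    key <- paste(signif(m, 12), accuracy)
    uk <- !duplicated(key)
    conf_u <- mapply(function(mm, acc) {
      .belief_conf_conditional(mm, sigma, correct = acc == 1, bound = bound)
    }, m[uk], accuracy[uk])
    conf <- conf_u[match(key, key[uk])]
  }
  data.frame(
    uncertainty = 1 - conf,
    complement_prediction_error = 1 - (accuracy - conf)
  )
}

#' @rdname predict_from_evidence
#' @param object an [sdt_model()].
#' @param ... passed on to [predict_from_evidence()].
#' @export
predict.sdt_model <- function(object, evidence, accuracy,
                              model = c("belief", "stimulus"), ...) {
  predict_from_evidence(evidence, accuracy, sigma = object$sigma,
                        model = match.arg(model), bound = object$bound)
}

#' Calibrate motion-energy scalars to evidence-strength units
#'
#' Motion energy is an arbitrary-unit estimate of delivered sensory
#' evidence. This maps it linearly onto \eqn{\mu} (coherence) units by
#' regressing the nominal |coherence| on |motion energy| (no intercept for
#' the magnitude relation would force 0 -> 0; a free intercept is kept to
#' absorb filter baseline, then applied to magnitudes and re-signed).
#'
#' @param motion_energy signed per-trial motion-energy scalars.
#' @param nominal_mu signed per-trial nominal evidence (direction x
#'   coherence).
#' @return signed calibrated evidence in \eqn{\mu} units (clipped to
#'   \[-0.5, 0.5\]).
#' @export
calibrate_evidence <- function(motion_energy, nominal_mu) {
  if (length(motion_energy) != length(nominal_mu))
    stop_param("inputs must have equal length")
  if (stats::var(abs(motion_energy)) == 0)
    stop_param("motion energy has zero variance; cannot calibrate")
  fit <- stats::lm(abs(nominal_mu) ~ abs(motion_energy))
  mag <- stats::predict(fit)
  mag <- pmin(pmax(mag, 0), 0.5)
  mag * sign1(motion_energy)
}
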