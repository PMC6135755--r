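# Observer model: choice rule, confidence read-outs, condition summaries,
# internal-noise estimation, evidence-conditioned predictions.

test_that("prob_correct implements the normal-CDF link", {
  expect_equal(prob_correct(0, 0.133), 0.5)
  # oracle: numeric integration of the standard normal density up to 1
  phi1 <- 0.5 + integrate(dnorm, 0, 1, rel.tol = 1e-12)$value
  expect_equal(prob_correct(0.133, 0.133), phi1, tolerance = 1e-10)
  expect_equal(prob_correct(10, 0.133), 1, tolerance = 1e-12)
  # monotone in distance
  x <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(prob_correct(x, 0.133)) > 0))
  expect_error(prob_correct(0.1, -1), "sigma")
  expect_error(prob_correct(-0.1, 0.1), "non-negative")
})

test_that("uncertainty and prediction error are complements of confidence", {
  expect_identical(uncertainty(0.5), 0.5)
  expect_identical(uncertainty(1.0), 0)
  phi1 <- pnorm(1)
  expect_equal(uncertainty(phi1), 1 - phi1)
  expect_error(uncertainty(1.2), "\\[0, 1\\]")
  expect_identical(prediction_error(1, 0.5), 0.5)
  expect_identical(prediction_error(0, 0.8), -0.8)
  expect_equal(prediction_error(1, phi1), 1 - phi1)
  expect_error(prediction_error(0.5, 0.5), "binary")
})

test_that("simulated trials follow the generative model", {
  m <- sdt_model(sigma = 0.133)
  tr <- simulate(m, nsim = 10000, seed = 1, mu = 0.5)
  # closed-form accuracy Phi(|mu|/sigma)
  expect_equal(mean(tr$correct), pnorm(0.5 / 0.133), tolerance = 1e-3)
  # stimulus-state confidence depends only on mu
  tr2 <- simulate(m, nsim = 200, seed = 2, mu = 0.07)
  expect_true(all(tr2$confidence_stimulus == prob_correct(0.07, 0.133)))
  # determinism
  tr3 <- simulate(m, nsim = 200, seed = 2, mu = 0.07)
  expect_identical(tr2, tr3)
  # belief confidence + uncertainty = 1 at machine precision
  expect_equal(tr$confidence_belief + tr$uncertainty, rep(1, nrow(tr)))
  # accuracy scoring: correct iff signs agree (sign(0) = +1)
  expect_identical(tr$correct,
                   as.integer(sign(tr$dv) == sign(tr$mu) |
                                (tr$dv == 0 & tr$mu > 0)))
  expect_error(simulate(m, mu = numeric(0)), "at least one")
  expect_error(simulate(m, mu = 0.7), "0.5")
})

test_that("accuracy matches Phi(|mu|/sigma) across the grid", {
  m <- sdt_model(sigma = 0.133)
  for (mu in c(0.02, 0.07, 0.14, 0.3)) {
    tr <- simulate(m, nsim = 10000, seed = 10 + round(100 * mu), mu = mu)
    p <- pnorm(mu / 0.133)
    expect_equal(mean(tr$correct), p,
                 tolerance = 4 * sqrt(p * (1 - p) / 10000) / p)
  }
})

test_that("condition summaries reproduce the diagnostic sign pattern", {
  m <- sdt_model(sigma = 0.133)
  tr <- simulate(m, nsim = 50000, seed = 3, mu = c(-MU_EASY, -MU_HARD,
                                                   MU_HARD, MU_EASY))
  # stimulus-state uncertainty: identical for correct and error at fixed |mu|
  ss <- summarize_conditions(tr, "stimulus", "uncertainty",
                             easy_mus = MU_EASY, hard_mus = MU_HARD)
  expect_identical(ss$interaction, 0)
  # belief state: positive uncertainty interaction, negative 1-PE interaction
  su <- summarize_conditions(tr, "belief", "uncertainty",
                             easy_mus = MU_EASY, hard_mus = MU_HARD)
  sp <- summarize_conditions(tr, "belief", "complement_prediction_error",
                             easy_mus = MU_EASY, hard_mus = MU_HARD)
  expect_gt(su$interaction, 0)
  expect_lt(sp$interaction, 0)
})

test_that("condition summaries equal a brute-force group-by oracle", {
  m <- sdt_model(sigma = 0.133)
  tr <- simulate(m, nsim = 2000, seed = 4, mu = c(-MU_EASY, MU_HARD, MU_EASY))
  su <- summarize_conditions(tr, "belief", "uncertainty",
                             easy_mus = MU_EASY, hard_mus = MU_HARD)
  diffi <- ifelse(abs(abs(tr$mu) - MU_EASY) < 1e-9, "Easy", "Hard")
  acc <- ifelse(tr$correct == 1, "Correct", "Error")
  oracle <- tapply(1 - tr$confidence_belief, paste(diffi, acc, sep = "-"), mean)
  expect_equal(su$cell_means[names(oracle)], oracle, ignore_attr = TRUE)
  expect_equal(su$interaction,
               unname((oracle[["Easy-Error"]] - oracle[["Easy-Correct"]]) -
                        (oracle[["Hard-Error"]] - oracle[["Hard-Correct"]])))
})

test_that("empty condition cells raise an error naming the cell", {
  m <- sdt_model(sigma = 0.01)  # almost no errors at easy coherence
  tr <- simulate(m, nsim = 20, seed = 5, mu = c(MU_HARD, MU_EASY))
  expect_error(
    summarize_conditions(tr, "belief", "uncertainty",
                         easy_mus = MU_EASY, hard_mus = MU_HARD),
    "Easy-Error")
  tr2 <- simulate(m, nsim = 20, seed = 5, mu = MU_EASY)
  expect_error(
    summarize_conditions(tr2, "belief", "uncertainty",
                         easy_mus = 0.9 * MU_EASY, hard_mus = MU_HARD),
    "neither")
})

test_that("probit fit recovers internal noise and rejects degenerate data", {
  m <- sdt_model(sigma = 0.133)
  mus <- rep(seq(-0.3, 0.3, by = 0.05), each = 1)
  tr <- simulate(m, nsim = 5000, seed = 6, mu = setdiff(mus, 0))
  fit <- fit_internal_noise(tr$mu, tr$choice)
  expect_equal(fit$sigma_hat, 1 / fit$beta)           # identity, exact
  expect_equal(fit$sigma_hat, 0.133, tolerance = 0.1) # parameter recovery
  # degenerate inputs
  expect_error(fit_internal_noise(c(-0.2, -0.1, 0.1, 0.2), rep(1, 4)),
               "identical")
  expect_error(fit_internal_noise(rep(0.1, 10), rep(c(-1, 1), 5)),
               "distinct")
  # noiseless separable data: slope diverges
  mu <- rep(c(-0.4, -0.2, 0.2, 0.4), each = 50)
  expect_error(fit_internal_noise(mu, sign(mu)), "separable")
})

test_that("evidence-conditioned predictions match a simulation oracle", {
  sigma <- 0.133
  # stimulus model at zero evidence: uncertainty 0.5 regardless of accuracy
  p <- predict_from_evidence(c(0, 0), c(0, 1), sigma, "stimulus")
  expect_equal(p$uncertainty, c(0.5, 0.5))
  # belief model: conditional mean of 1 - f(|dv|) given the accuracy region
  set.seed(11)
  ev <- 0.1
  dv <- rnorm(4e5, ev, sigma)
  unc <- 1 - pnorm(abs(dv) / sigma)
  oracle_err <- mean(unc[dv < 0])
  oracle_cor <- mean(unc[dv >= 0])
  pb <- predict_from_evidence(c(ev, ev), c(0, 1), sigma, "belief")
  expect_equal(pb$uncertainty[1], oracle_err, tolerance = 0.01)
  expect_equal(pb$uncertainty[2], oracle_cor, tolerance = 0.01)
  # error-trial uncertainty increases with |evidence|, correct decreases
  evs <- c(0.05, 0.1, 0.2, 0.3)
  pe <- predict_from_evidence(evs, rep(0, 4), sigma, "belief")
  pc <- predict_from_evidence(evs, rep(1, 4), sigma, "belief")
  expect_true(all(diff(pe$uncertainty) > 0))
  expect_true(all(diff(pc$uncertainty) < 0))
  # complement of the prediction error is 1 - (feedback - confidence)
  expect_equal(pb$complement_prediction_error,
               1 - (c(0, 1) - (1 - pb$uncertainty)))
  expect_warning(predict_from_evidence(0.7, 1, sigma, "stimulus"),
                 "clipping")
})

test_that("motion-energy calibration maps back to coherence units", {
  set.seed(12)
  mu <- sample(c(-MU_EASY, -MU_HARD, MU_HARD, MU_EASY), 400, replace = TRUE)
  me <- 3.5 * mu + rnorm(400, 0, 0.05)   # arbitrary-unit evidence
  cal <- calibrate_evidence(me, mu)
  expect_true(all(abs(cal) <= 0.5))
  expect_gt(cor(cal, mu), 0.8)
  fit <- lm(abs(mu) ~ abs(cal))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)
})
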