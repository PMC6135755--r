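# Inferential layer: cluster permutation, RM-ANOVA, paired permutation,
# RT residualization, evidence regressions, model-pupil correlations.

test_that("cluster permutation finds constructed effects and nothing in zeros", {
  # all-zero contrasts: no clusters
  cr0 <- cluster_permutation(matrix(0, 10, 30), n_perm = 200, seed = 1)
  expect_equal(nrow(cr0$clusters), 0)
  # constant large offset: one cluster spanning the window at the p floor
  set.seed(2)
  X <- matrix(5 + rnorm(15 * 40, 0, 0.1), 15, 40)
  cr <- cluster_permutation(X, time = seq(0, 3.9, by = 0.1), n_perm = 500,
                            seed = 3)
  expect_equal(nrow(cr$clusters), 1)
  expect_equal(cr$clusters$start_s, 0)
  expect_equal(cr$clusters$end_s, 3.9)
  expect_equal(cr$clusters$p_value, 1 / 501)
  # localized effect is localized
  Y <- matrix(rnorm(15 * 60), 15, 60)
  Y[, 25:35] <- Y[, 25:35] + 2
  cr2 <- cluster_permutation(Y, n_perm = 500, seed = 4)
  sig <- cr2$clusters[cr2$clusters$p_value < 0.05, ]
  expect_equal(nrow(sig), 1)
  expect_true(sig$start_s >= 20 && sig$end_s <= 40)
  expect_error(cluster_permutation(Y[1:3, ]), "5 subjects")
  expect_error(cluster_permutation(Y, n_perm = 50), "at least 100")
})

test_that("RM-ANOVA reduces to the squared paired t for 2x2 designs", {
  set.seed(5)
  d <- expand.grid(subject = 1:12, difficulty = c("Easy", "Hard"),
                   accuracy = c("Correct", "Error"))
  d$value <- rnorm(nrow(d)) + (d$difficulty == "Hard") * 0.4 +
    (d$difficulty == "Hard") * (d$accuracy == "Error") * 0.6
  an <- rm_anova_2x2(d)
  m <- tapply(d$value, list(d$subject, paste(d$difficulty, d$accuracy)), mean)
  isc <- (m[, "Easy Error"] - m[, "Easy Correct"]) -
    (m[, "Hard Error"] - m[, "Hard Correct"])
  expect_equal(an$table["interaction", "F"],
               unname(t.test(isc)$statistic^2), tolerance = 1e-10)
  expect_equal(an$table["interaction", "df1"], 1)
  expect_equal(an$table["interaction", "df2"], 11)
  # additive cell means: interaction sum of squares is exactly 0
  d2 <- d
  d2$value <- as.numeric(d2$subject) * 0.1 + (d2$difficulty == "Hard") * 1 +
    (d2$accuracy == "Error") * 2
  an2 <- rm_anova_2x2(d2)
  expect_equal(an2$table["interaction", "ss"], 0, tolerance = 1e-20)
  expect_error(rm_anova_2x2(d[-1, ]), "incomplete")
})

test_that("paired permutation test matches exhaustive enumeration", {
  set.seed(6)
  x <- rnorm(10, 0.4)
  res <- permutation_test_paired(x, 0, exact = TRUE)
  # independent brute-force oracle over all 2^10 sign patterns
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  p_oracle <- mean(abs(signs %*% x / 10) >= abs(mean(x)) - 1e-12)
  expect_equal(res$p_value, p_oracle)
  # Monte-Carlo agrees within permutation standard error
  mc <- permutation_test_paired(x, 0, n_perm = 20000, seed = 7,
                                exact = FALSE)
  expect_equal(mc$p_value, p_oracle,
               tolerance = 4 * sqrt(p_oracle * (1 - p_oracle) / 20000) /
                 max(p_oracle, 1e-6))
  # identical vectors: p = 1 with warning
  expect_warning(r0 <- permutation_test_paired(x, x), "zero-variance")
  expect_equal(r0$p_value, 1)
  # overwhelming effect bottoms out at the resolution floor
  big <- permutation_test_paired(rep(10, 20) + rnorm(20, 0, 0.01), 0,
                                 n_perm = 10000, seed = 8, exact = FALSE)
  expect_equal(big$p_value, 1 / 10001)
})

test_that("permutation p-values are stable in n_perm", {
  set.seed(9)
  x <- rnorm(12, 0.3)
  p1 <- permutation_test_paired(x, 0, n_perm = 5000, seed = 10,
                                exact = FALSE)$p_value
  p2 <- permutation_test_paired(x, 0, n_perm = 10000, seed = 11,
                                exact = FALSE)$p_value
  se <- sqrt(p1 * (1 - p1) / 5000)
  expect_lt(abs(p1 - p2), 5 * se + 1e-4)
})

test_that("RT residualization matches closed-form hat-matrix residuals", {
  set.seed(12)
  n <- 80
  rt <- runif(n, 0.5, 2)
  subj <- rep(1, n)
  # pupil exactly linear in RT: residual variance ~ 0
  pup <- 3 + 2 * rt
  out <- residualize_rt(pup, rt, subj)
  expect_lt(var(out), 1e-20)
  expect_equal(mean(out), mean(pup))
  # orthogonal pupil: unchanged
  pup2 <- rnorm(n)
  pup2 <- pup2 - coef(lm(pup2 ~ rt))[2] * rt  # force orthogonality
  out2 <- residualize_rt(pup2, rt, subj)
  expect_equal(out2, pup2 + mean(pup2) - mean(pup2), tolerance = 1e-10)
  # hat-matrix oracle
  pup3 <- rnorm(n) + rt
  X <- cbind(1, rt)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  oracle <- as.numeric((diag(n) - H) %*% pup3) + mean(pup3)
  expect_equal(residualize_rt(pup3, rt, subj), oracle, tolerance = 1e-10)
  expect_warning(residualize_rt(pup3, rep(1, n), subj), "constant RT")
})

test_that("evidence regressions recover planted slopes per accuracy class", {
  set.seed(13)
  n_sub <- 8; n_tr <- 200
  subj <- rep(1:n_sub, each = n_tr)
  ev <- runif(n_sub * n_tr, 0, 0.5)
  acc <- rep(rep(0:1, each = n_tr / 2), n_sub)
  # +1 slope on errors, -1 on correct -> interaction ~ 2
  pup <- ifelse(acc == 0, ev, -ev) + rnorm(n_sub * n_tr, 0, 0.01)
  ri <- regress_on_evidence(pup, ev, acc, subj, n_perm = 2000, seed = 14)
  expect_equal(ri$mean, 2, tolerance = 0.05)
  expect_lt(ri$p_value, 0.01)
  # evidence-independent pupil -> interaction ~ 0
  pup0 <- rnorm(n_sub * n_tr, 0, 0.1)
  ri0 <- regress_on_evidence(pup0, ev, acc, subj, n_perm = 2000, seed = 15)
  expect_equal(ri0$mean, 0, tolerance = 0.15)
  # subjects under the trial minimum are excluded
  acc2 <- acc; acc2[subj == 1] <- 1
  expect_message(
    ri2 <- regress_on_evidence(pup, ev, acc2, subj, n_perm = 500, seed = 16),
    "excluded")
  expect_equal(nrow(ri2$betas), n_sub - 1)
})

test_that("model-pupil correlations hit the trivial fixed points", {
  set.seed(17)
  n_sub <- 6; n_tr <- 60
  subj <- rep(1:n_sub, each = n_tr)
  pred <- runif(n_sub * n_tr)
  # pupil identical to the prediction: r = 1 for every subject
  mc <- model_pupil_correlation(pred, pred, subj, scheme = "single_trial",
                                n_perm = 500, seed = 18)
  expect_equal(mc$r$r, rep(1, n_sub))
  mc2 <- model_pupil_correlation(pred, -pred, subj, scheme = "single_trial",
                                 n_perm = 500, seed = 18)
  expect_equal(mc2$r$r, rep(-1, n_sub))
  # six-bin scheme: r = 1 when pupil is a monotone function of the prediction
  mc3 <- model_pupil_correlation(pred, 2 * pred + 1, subj, scheme = "six_bin",
                                 n_perm = 500, seed = 18)
  expect_equal(mc3$r$r, rep(1, n_sub), tolerance = 1e-10)
  expect_error(
    model_pupil_correlation(pred[1:30], pred[1:30], rep(1:6, each = 5),
                            scheme = "six_bin", n_bins = 6),
    "fewer")
})

test_that("equal-count binning balances bins to within one trial", {
  set.seed(19)
  for (n_bins in c(4, 6)) {
    v <- rnorm(53)
    bins <- pupilstate:::.equal_count_bins(v, n_bins)
    counts <- table(bins)
    expect_equal(length(counts), n_bins)
    expect_lte(diff(range(counts)), 1)
    # ties broken by stable order
    vt <- rep(1, 12)
    bt <- pupilstate:::.equal_count_bins(vt, 4)
    expect_equal(bt, rep(1:4, each = 3))
  }
})

test_that("four-condition correlations compare the two models coherently", {
  set.seed(20)
  n_sub <- 8; n_tr <- 120
  subj <- rep(1:n_sub, each = n_tr)
  diffi <- sample(c("Easy", "Hard"), n_sub * n_tr, replace = TRUE)
  acc <- rbinom(n_sub * n_tr, 1, ifelse(diffi == "Easy", 0.85, 0.70))
  pred <- ifelse(diffi == "Hard", 0.3, 0.15) + (1 - acc) * 0.2
  pup <- pred * 3 + rnorm(n_sub * n_tr, 0, 0.05)
  mc <- model_pupil_correlation(pred, pup, subj, scheme = "four_condition",
                                difficulty = diffi, accuracy = acc,
                                n_perm = 1000, seed = 21)
  expect_gt(mc$mean_r, 0.9)
  expect_lt(mc$p_value, 0.05)
  pred_flat <- ifelse(diffi == "Hard", 0.3, 0.15)  # accuracy-blind model
  mc0 <- model_pupil_correlation(pred_flat, pup, subj,
                                 scheme = "four_condition",
                                 difficulty = diffi, accuracy = acc,
                                 n_perm = 1000, seed = 21)
  cmp <- compare_model_correlations(mc, mc0, n_perm = 1000, seed = 22)
  expect_gt(cmp$mean_diff_r, 0)
})
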