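#' Cluster-based permutation test on paired time courses
#'
#' Tests a per-subject contrast time course against zero while controlling
#' the family-wise error over time points. A paired t statistic is computed
#' at each time point; contiguous runs of samples exceeding the
#' cluster-forming threshold (two-tailed t critical value at
#' `alpha_cluster`) form clusters scored by their summed t (cluster mass).
#' The null distribution of the maximum absolute cluster mass is built by
#' randomly sign-flipping whole subjects; cluster p-values are the
#' fraction of null maxima at least as large as the observed mass
#' (add-one corrected).
#'
#' @param contrasts subjects x time matrix of per-subject contrast values.
#' @param time time axis, s (default sample indices).
#' @param alpha_cluster cluster-forming threshold as a two-tailed p
#'   (default 0.05).
#' @param n_perm number of sign-flip permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @return An object of class `"cluster_result"`: data.frame `clusters`
#'   (`start_s`, `end_s`, `mass`, `p_value`), plus `threshold`, `n_perm`,
#'   `seed`, `t_values`, `time`.
#' @export
cluster_permutation <- function(contrasts, time = NULL, alpha_cluster = 0.05,
                                n_perm = 1000, seed = 1L) {
  X <- as.matrix(contrasts)
  ns <- nrow(X)
  if (ns < 5) stop_param("need at least 5 subjects")
  if (n_perm < 100) stop_param("n_perm must be at least 100")
  if (is.null(time)) time <- seq_len(ncol(X))
  if (length(time) != ncol(X)) stop_param("time axis length mismatch")
  thr <- stats::qt(1 - alpha_cluster / 2, df = ns - 1)
  tstat <- function(M, S = NULL) {
    # paired t per column, optionally under sign flips S (n_perm x ns)
    if (is.null(S)) {
      m <- colMeans(M)
      v <- (colMeans(M^2) - m^2) * ns / (ns - 1)
      tt <- m / sqrt(v / ns)
      tt[is.nan(tt)] <- 0   # zero mean and zero variance: no evidence
      tt
    } else {
      mm <- (S %*% M) / ns                      # n_perm x T
      msq <- matrix(colMeans(M^2), nrow(S), ncol(M), byrow = TRUE)
      v <- (msq - mm^2) * ns / (ns - 1)
      tt <- mm / sqrt(v / ns)
      tt[is.nan(tt)] <- 0
      tt
    }
  }
  find_clusters <- function(tv) {
    # runs of supra-threshold samples of consistent sign
    out <- list()
    for (sgn in c(1, -1)) {
      supra <- sgn * tv > thr
      if (!any(supra)) next
      r <- rle(supra)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        out[[length(out) + 1L]] <- list(i1 = starts[k], i2 = ends[k],
                                        mass = sum(tv[starts[k]:ends[k]]))
      }
    }
    out
  }
  tv <- tstat(X)
  obs <- find_clusters(tv)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE), n_perm, ns)
    Tm <- tstat(X, S)
    apply(Tm, 1, function(row) {
      cl <- find_clusters(row)
      if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "mass"))) else 0
    })
  })
  clusters <- if (length(obs)) {
    df <- data.frame(
      start_s = time[vapply(obs, `[[`, integer(1), "i1")],
      end_s = time[vapply(obs, `[[`, integer(1), "i2")],
      mass = vapply(obs, `[[`, numeric(1), "mass")
    )
    df$p_value <- vapply(df$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
    df <- df[order(df$start_s), ]
    rownames(df) <- NULL
    df
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0), mass = numeric(0),
               p_value = numeric(0))
  }
  structure(list(clusters = clusters, threshold = thr,
                 alpha_cluster = alpha_cluster, n_perm = n_perm, seed = seed,
                 t_values = tv, time = time, n_subjects = ns),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster-based permutation test (%d subjects, %d permutations, |t| > %.2f)\n",
              x$n_subjects, x$n_perm, x$threshold))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}

#' Two-way repeated-measures ANOVA on a 2x2 within-subject design
#'
#' F tests for the main effects of difficulty and accuracy and their
#' interaction on per-subject cell means, with subject as the random
#' factor. For 2-level factors each effect F equals the squared paired t on
#' the corresponding per-subject contrast.
#'
#' @param cells data.frame with columns `subject`, `difficulty`
#'   (Easy/Hard), `accuracy` (Correct/Error), `value` -- one row per
#'   subject x cell (complete).
#' @return An object of class `"anova_2x2"`: data.frame `table` with rows
#'   difficulty, accuracy, interaction; columns `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(cells) {
  need <- c("subject", "difficulty", "accuracy", "value")
  if (!all(need %in% names(cells)))
    stop_param("'cells' must have columns ", paste(need, collapse = ", "))
  tab <- table(cells$subject, cells$difficulty, cells$accuracy)
  if (any(tab != 1L)) {
    bad <- dimnames(tab)[[1]][apply(tab != 1L, 1, any)]
    stop_param("incomplete 2x2 cells for subject(s): ",
               paste(bad, collapse = ", "))
  }
  d <- cells
  d$subject <- factor(d$subject)
  d$difficulty <- factor(d$difficulty)
  d$accuracy <- factor(d$accuracy)
  fit <- stats::aov(value ~ difficulty * accuracy +
                      Error(subject / (difficulty * accuracy)), data = d)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tb <- sm[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tb)), fixed = TRUE)[1]
    c(F = tb[i, "F value"], df1 = tb[i, "Df"],
      df2 = tb[nrow(tb), "Df"], p = tb[i, "Pr(>F)"], ss = tb[i, "Sum Sq"])
  }
  res <- rbind(
    difficulty = pick("Error: subject:difficulty", "difficulty"),
    accuracy = pick("Error: subject:accuracy", "accuracy"),
    interaction = pick("Error: subject:difficulty:accuracy", "difficulty:accuracy")
  )
  structure(list(table = as.data.frame(res),
                 n_subjects = nlevels(d$subject)), class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA (%d subjects)\n", x$n_subjects))
  tb <- x$table
  tb$F <- round(tb$F, 3); tb$p <- signif(tb$p, 3)
  print(tb)
  invisible(x)
}

#' Paired (sign-flip) permutation test
#'
#' Two-tailed non-parametric test of paired differences (or of a single
#' sample against zero). The statistic is the mean difference; the null is
#' built by randomly flipping the sign of each pair's difference. With
#' `exact = TRUE` (or whenever all 2^n sign patterns fit within `n_perm`)
#' the full enumeration is used and the p-value is exact; otherwise the
#' Monte-Carlo p-value with add-one correction is returned.
#'
#' @param x numeric vector.
#' @param y paired vector or scalar reference (default 0).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed RNG seed (Monte-Carlo only).
#' @param exact force/forbid exhaustive enumeration (default: automatic).
#' @return list with `p_value`, `statistic` (mean difference), `method`.
#' @export
permutation_test_paired <- function(x, y = 0, n_perm = 10000, seed = 1L,
                                    exact = NULL) {
  d <- x - y
  n <- length(d)
  if (n < 5) stop_param("need at least 5 pairs")
  if (all(d == 0)) {
    warning("zero-variance differences; p = 1", call. = FALSE)
    return(list(p_value = 1, statistic = 0, method = "degenerate"))
  }
  obs <- mean(d)
  use_exact <- if (is.null(exact)) n <= 20 && 2^n <= n_perm else exact
  eps <- 1e-12
  if (use_exact) {
    if (n > 25) stop_param("exact enumeration infeasible for n > 25")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats_null <- as.numeric(signs %*% d) / n
    p <- mean(abs(stats_null) >= abs(obs) - eps)
    method <- "exact sign-flip enumeration"
  } else {
    stats_null <- with_seed(seed, {
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      as.numeric(S %*% d) / n
    })
    p <- (1 + sum(abs(stats_null) >= abs(obs) - eps)) / (n_perm + 1)
    method <- "Monte-Carlo sign-flip"
  }
  list(p_value = p, statistic = obs, method = method)
}

#' Remove reaction-time variance from pupil scalars or time courses
#'
#' Within each subject, regresses the pupil measure on RT by least squares
#' and keeps the residuals, with the subject's mean re-added so values stay
#' in interpretable percent-signal-change units. Matrices are residualized
#' column-wise (per time point). Subjects with constant RT are passed
#' through unchanged with a warning.
#'
#' @param pupil numeric vector or trials x time matrix.
#' @param rt per-trial reaction times, s.
#' @param subject per-trial subject ids.
#' @return object of the same shape as `pupil`.
#' @export
residualize_rt <- function(pupil, rt, subject) {
  mat <- is.matrix(pupil)
  P <- if (mat) pupil else matrix(pupil, ncol = 1)
  if (nrow(P) != length(rt) || length(rt) != length(subject))
    stop_param("pupil, rt and subject must agree in length")
  out <- P
  for (s in unique(subject)) {
    sel <- subject == s
    r <- rt[sel]
    if (stats::var(r) == 0) {
      warning("constant RT for subject ", s, "; returned unchanged",
              call. = FALSE)
      next
    }
    Xd <- cbind(1, r)
    B <- solve(crossprod(Xd), crossprod(Xd, P[sel, , drop = FALSE]))
    resid <- P[sel, , drop = FALSE] - Xd %*% B
    out[sel, ] <- sweep(resid, 2, colMeans(P[sel, , drop = FALSE]), `+`)
  }
  if (mat) out else as.numeric(out)
}

#' Regression of pupil responses on evidence strength, by accuracy
#'
#' Within each subject, regresses the (RT-corrected) pupil measure on
#' absolute evidence strength (absolute motion energy) separately for
#' error and correct trials. The diagnostic interaction is the difference
#' in slopes, beta(Error) - beta(Correct); group inference is a paired
#' sign-flip permutation test of the per-subject interactions against 0.
#'
#' @param pupil per-trial scalar.
#' @param abs_evidence per-trial absolute evidence strength.
#' @param accuracy per-trial 0/1.
#' @param subject per-trial subject ids.
#' @param min_trials minimum trials per accuracy class per subject
#'   (default 10); subjects below it are excluded.
#' @param n_perm,seed permutation parameters for the group test.
#' @return An object of class `"regression_interaction"`: data.frame
#'   `betas` (`subject`, `beta_error`, `beta_correct`, `interaction`),
#'   group `mean`, `sd`, `p_value`, `excluded`.
#' @export
regress_on_evidence <- function(pupil, abs_evidence, accuracy, subject,
                                min_trials = 10, n_perm = 10000, seed = 1L) {
  stopifnot(length(pupil) == length(abs_evidence),
            length(pupil) == length(accuracy),
            length(pupil) == length(subject))
  rows <- list(); excluded <- character(0)
  for (s in unique(subject)) {
    sel <- subject == s
    ne <- sum(sel & accuracy == 0); nc <- sum(sel & accuracy == 1)
    if (ne < min_trials || nc < min_trials) {
      excluded <- c(excluded, as.character(s)); next
    }
    slope <- function(cls) {
      ss <- sel & accuracy == cls
      unname(stats::coef(stats::lm(pupil[ss] ~ abs_evidence[ss]))[2])
    }
    be <- slope(0); bc <- slope(1)
    rows[[length(rows) + 1L]] <- data.frame(subject = s, beta_error = be,
                                            beta_correct = bc,
                                            interaction = be - bc)
  }
  if (length(excluded))
    message("subjects excluded (<", min_trials, " trials per class): ",
            paste(excluded, collapse = ", "))
  if (length(rows) < 5)
    stop_param("fewer than 5 subjects with enough trials per class")
  betas <- do.call(rbind, rows)
  gt <- permutation_test_paired(betas$interaction, 0, n_perm = n_perm,
                                seed = seed)
  structure(list(betas = betas, mean = mean(betas$interaction),
                 sd = stats::sd(betas$interaction), p_value = gt$p_value,
                 excluded = excluded), class = "regression_interaction")
}

#' @export
print.regression_interaction <- function(x, ...) {
  cat(sprintf("Evidence-strength regression interaction (beta Error - beta Correct)\n"))
  cat(sprintf("  group mean %.4g (sd %.4g), permutation p = %.4g, n = %d subjects\n",
              x$mean, x$sd, x$p_value, nrow(x$betas)))
  invisible(x)
}

# equal-count bins by within-subject quantile rank; ties broken by stable
# trial order
.equal_count_bins <- function(v, n_bins) {
  n <- length(v)
  if (n < n_bins) stop_param("fewer trials (", n, ") than bins (", n_bins, ")")
  ord <- order(v)  # stable for ties
  bins <- integer(n)
  bins[ord] <- ceiling(seq_len(n) * n_bins / n)
  bins
}

#' Correlate model predictions with pupil responses
#'
#' Per-subject Pearson correlation between a model-derived variable
#' (uncertainty or complement of prediction error) and a pupil scalar,
#' under one of three schemes: `"four_condition"` correlates the 2x2
#' Difficulty x Accuracy cell means; `"six_bin"` bins trials within
#' subject into equal-count bins of the model variable and correlates bin
#' means (used on error trials only); `"single_trial"` correlates
#' trial-wise values. Group inference is a sign-flip permutation test on
#' the Fisher-z transformed correlations.
#'
#' @param model_pred per-trial model predictions.
#' @param pupil per-trial pupil scalars.
#' @param subject per-trial subject ids.
#' @param scheme correlation scheme.
#' @param difficulty,accuracy required for `"four_condition"`.
#' @param n_bins bins for `"six_bin"` (default 6).
#' @param n_perm,seed group permutation parameters.
#' @return An object of class `"model_pupil_cor"`: data.frame `r` per
#'   subject, group `mean_r`, `p_value`.
#' @export
model_pupil_correlation <- function(model_pred, pupil, subject,
                                    scheme = c("four_condition", "six_bin",
                                               "single_trial"),
                                    difficulty = NULL, accuracy = NULL,
                                    n_bins = 6, n_perm = 10000, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(length(model_pred) == length(pupil),
            length(pupil) == length(subject))
  rs <- numeric(0); subs <- c()
  for (s in unique(subject)) {
    sel <- subject == s
    r <- switch(scheme,
      four_condition = {
        if (is.null(difficulty) || is.null(accuracy))
          stop_param("four_condition scheme needs difficulty and accuracy")
        acc <- accuracy[sel]
        if (is.numeric(acc)) acc <- ifelse(acc == 1, "Correct", "Error")
        key <- paste(difficulty[sel], acc, sep = ".")
        cells <- c("Easy.Correct", "Easy.Error", "Hard.Correct", "Hard.Error")
        if (!all(cells %in% key)) NA_real_
        else {
          mp <- vapply(cells, function(cl) mean(model_pred[sel][key == cl]),
                       numeric(1))
          pp <- vapply(cells, function(cl) mean(pupil[sel][key == cl]),
                       numeric(1))
          stats::cor(mp, pp)
        }
      },
      six_bin = {
        bins <- .equal_count_bins(model_pred[sel], n_bins)
        mp <- tapply(model_pred[sel], bins, mean)
        pp <- tapply(pupil[sel], bins, mean)
        stats::cor(mp, pp)
      },
      single_trial = stats::cor(model_pred[sel], pupil[sel])
    )
    if (!is.na(r)) { rs <- c(rs, r); subs <- c(subs, s) }
  }
  if (length(rs) < 5) stop_param("fewer than 5 subjects with a defined r")
  z <- atanh(pmin(pmax(rs, -0.999999), 0.999999))
  gt <- permutation_test_paired(z, 0, n_perm = n_perm, seed = seed)
  structure(list(r = data.frame(subject = subs, r = rs),
                 scheme = scheme, mean_r = mean(rs),
                 p_value = gt$p_value), class = "model_pupil_cor")
}

#' @export
print.model_pupil_cor <- function(x, ...) {
  cat(sprintf("Model-pupil correlation (%s): mean r = %.3f, permutation p = %.4g (n = %d)\n",
              x$scheme, x$mean_r, x$p_value, nrow(x$r)))
  invisible(x)
}

#' Compare two sets of model-pupil correlations
#'
#' Paired sign-flip permutation test on the difference of Fisher-z
#' transformed per-subject correlations (e.g. belief-state vs
#' stimulus-state model).
#'
#' @param cor1,cor2 `"model_pupil_cor"` objects over the same subjects.
#' @param n_perm,seed permutation parameters.
#' @return list with `p_value`, `mean_diff_z`, `mean_diff_r`.
#' @export
compare_model_correlations <- function(cor1, cor2, n_perm = 10000, seed = 1L) {
  m <- merge(cor1$r, cor2$r, by = "subject", suffixes = c("_1", "_2"))
  if (nrow(m) < 5) stop_param("fewer than 5 shared subjects")
  clamp <- function(r) pmin(pmax(r, -0.999999), 0.999999)
  z1 <- atanh(clamp(m$r_1)); z2 <- atanh(clamp(m$r_2))
  gt <- permutation_test_paired(z1, z2, n_perm = n_perm, seed = seed)
  list(p_value = gt$p_value, mean_diff_z = mean(z1 - z2),
       mean_diff_r = mean(m$r_1 - m$r_2))
}
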