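make_linear_data <- function(m = 5, n = 12, slope = 2, intercept = 1,
                             noise = 0, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(m), function(j) {
    x <- seq(1, 9, length.out = n)
    tibble::tibble(participant = sprintf("p%02d", j), valence = x,
                   emg = intercept + slope * x + rnorm(n, 0, noise))
  }))
}

test_that("perfectly linear data are fit exactly with the variance at the boundary", {
  d <- make_linear_data(slope = 2, intercept = 1, noise = 0)
  fit <- fit_concordance_lmm(d)
  expect_equal(unname(fit$gamma), c(1, 2), tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-10)
  expect_true(fit$singular)
})

test_that("the ML fit matches lme4 on envelope-level simulated datasets", {
  skip_if_not_installed("lme4")
  for (s in 1:3) {
    ps <- simulate_paired_series(exp1_config(seed = s))
    d <- paired_from_series(ps, if (s %% 2) "cs" else "zm")
    fit <- fit_concordance_lmm(d)
    orc <- oracle_lmer(d, start_theta = theta_chol(fit))
    expect_lt(abs(fit$gamma[["valence"]] - orc$slope), 1e-3)
    expect_lt(abs(fit$loglik - orc$loglik), 1e-2)
    expect_true(fit$converged)
    # the mixed model can never fit worse than its nested pooled regression
    ols <- stats::logLik(lm(emg ~ valence, data = d))
    expect_gte(fit$loglik, as.numeric(ols) - 1e-6)
  }
})

test_that("with no random-effect variance the slope approaches the pooled OLS slope", {
  ps <- simulate_paired_series(exp1_config(seed = 31, intercept_sd = 0,
                                           slope_sd = 0),
                               standardize = FALSE)
  d <- paired_from_series(ps, "cs")
  fit <- fit_concordance_lmm(d)
  pooled <- coef(lm(emg ~ valence, data = d))[["valence"]]
  se <- sqrt(fit$vcov["valence", "valence"])
  expect_lt(abs(fit$gamma[["valence"]] - pooled), 3 * se)
})

test_that("degrees of freedom follow the m - l - 1 rule", {
  expect_identical(df_m_l_1(15, 0), 14)
  expect_identical(df_m_l_1(23, 0), 22)
  expect_identical(df_m_l_1(10, 3), 6)
  expect_error(df_m_l_1(4, 3), "m >= l \\+ 2")
})

test_that("one-tailed slope p-values match an independent tail-probability oracle", {
  # independent route: numerical integration of the t density
  t_tail <- function(q, df) {
    stats::integrate(function(u) stats::dt(u, df), -Inf, q,
                     rel.tol = 1e-10)$value
  }
  set.seed(50)
  for (i in 1:50) {
    beta <- rnorm(1, 0, 0.3)
    se <- runif(1, 0.01, 0.2)
    df <- sample(3:40, 1)
    fake <- structure(list(converged = TRUE, x = "valence",
                           gamma = c("(Intercept)" = 0, valence = beta),
                           vcov = matrix(c(1, 0, 0, se^2), 2, 2,
                                         dimnames = rep(list(c("(Intercept)", "valence")), 2))),
                      class = "concordance_model")
    neg <- slope_t_test(fake, df, "negative")
    pos <- slope_t_test(fake, df, "positive")
    expect_lt(abs(neg$p - t_tail(beta / se, df)), 1e-7)
    expect_equal(neg$p + pos$p, 1, tolerance = 1e-12)
    if (beta > 0) expect_gt(neg$p, 0.5)   # one-tailed orientation
  }
})

test_that("a non-converged model refuses a slope test", {
  fake <- structure(list(converged = FALSE, message = "iteration limit"),
                    class = "concordance_model")
  expect_error(slope_t_test(fake, 14, "negative"), "converge")
})

test_that("noise-free fits have no residual outliers", {
  set.seed(2)
  d <- dplyr::bind_rows(lapply(1:5, function(j) {
    x <- seq(1, 9, length.out = 20)
    tibble::tibble(participant = sprintf("p%02d", j), valence = x,
                   emg = rnorm(1) + (2 + rnorm(1, 0, 0.3)) * x)
  }))
  fit <- fit_concordance_lmm(d)
  res <- standardized_residuals(fit, d)
  expect_length(flag_outliers(res), 0)
})

test_that("an injected extreme point is flagged and its removal improves the slope", {
  set.seed(3)
  m <- 5; n <- 10; truth <- -0.5
  d <- dplyr::bind_rows(lapply(seq_len(m), function(j) {
    x <- runif(n, 1, 9)
    tibble::tibble(participant = sprintf("p%02d", j), valence = x,
                   emg = truth * x + rnorm(n, 0, 0.3))
  }))
  fit0 <- fit_concordance_lmm(d)
  res0 <- standardized_residuals(fit0, d)
  hit <- 17L
  d$emg[hit] <- d$emg[hit] + 10 * sqrt(fit0$sigma2)
  fit <- fit_concordance_lmm(d)
  res <- standardized_residuals(fit, d)
  expect_identical(flag_outliers(res), hit)

  ref <- refit_without_outliers(fit, d, direction = "negative")
  expect_identical(ref$outlier_idx, hit)
  expect_lte(abs(ref$test$beta - truth), abs(fit$gamma[["valence"]] - truth))
  # removing a point the model did not generate cannot lower the fit quality
  expect_gte(ref$model$loglik / ref$model$n_obs,
             fit$loglik / fit$n_obs)
  expect_true(ref$outlier_pct >= 0 && ref$outlier_pct <= 100)
})

test_that("outlier refits keep short participants rather than dropping below 3 obs", {
  set.seed(4)
  d <- make_linear_data(m = 4, n = 12, noise = 0.2, seed = 4)
  short <- tibble::tibble(participant = "p99", valence = c(2, 5, 8),
                          emg = c(5, 11, 30))   # third point far off the line
  d <- dplyr::bind_rows(d, short)
  fit <- fit_concordance_lmm(d)
  res <- standardized_residuals(fit, d)
  if (length(flag_outliers(res)) > 0 &&
      any(d$participant[flag_outliers(res)] == "p99")) {
    expect_warning(refit_without_outliers(fit, d, direction = "positive"),
                   "retained")
  } else {
    succeed("no outlier landed on the short participant in this layout")
  }
})

test_that("lagged correlations recover constructed shifts and signs", {
  x <- simulate_valence_trace(200, 10, seed = 12)
  expect_equal(zero_lag_correlation(x, x), 1)
  expect_equal(zero_lag_correlation(x, -x), -1)
  expect_true(is.na(zero_lag_correlation(x, rep(5, 200))))

  y <- c(rep(NA, 3), head(x, -3))   # y trails x by 3 s
  cc <- cross_correlation(x, y, max_lag_s = 6)
  expect_equal(cc$lag_s[which.max(cc$r)], 3)
  expect_equal(max(cc$r, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("group-mean summaries average participants and fit the exact line", {
  d1 <- tibble::tibble(participant = "p01", trial_id = 1, t_s = 0:9,
                       valence = seq(2, 8, length.out = 10),
                       emg = seq(-1, 1, length.out = 10))
  d2 <- d1; d2$participant <- "p02"
  gs <- group_summary(dplyr::bind_rows(d1, d2))
  expect_equal(gs$table$mean_y, d1$emg)

  # pooled noiseless linear data: group-mean regression = generating line
  expect_equal(unname(gs$coef["slope"]), 2 / 6, tolerance = 1e-9)

  # coefficients match the closed-form least-squares solution
  tab <- gs$table
  sl <- sum((tab$mean_x - mean(tab$mean_x)) * (tab$mean_y - mean(tab$mean_y))) /
    sum((tab$mean_x - mean(tab$mean_x))^2)
  expect_equal(unname(gs$coef["slope"]), sl, tolerance = 1e-12)
  expect_equal(unname(gs$coef["intercept"]), mean(tab$mean_y) - sl * mean(tab$mean_x),
               tolerance = 1e-12)
})

test_that("adding an independent sex covariate changes df and little else", {
  ps <- simulate_paired_series(exp1_config(seed = 77, n_participants = 15))
  d <- paired_from_series(ps, "cs")
  pids <- unique(d$participant)
  set.seed(78)
  sex <- stats::setNames(sample(rep(c("f", "m"), length.out = length(pids))),
                         pids)
  out <- sex_covariate_sensitivity(d, sex, direction = "negative")
  expect_identical(out$adjusted_test$df, 13)
  expect_identical(out$base_test$df, 14)
  expect_lt(abs(out$adjusted_test$beta - out$base_test$beta),
            2 * out$base_test$se)
  expect_true(out$covariate_p > 0 && out$covariate_p < 1)
  expect_true(out$significance_unchanged)

  expect_error(sex_covariate_sensitivity(d, stats::setNames(rep("f", 15), pids)),
               "single level")
})

test_that("the sex-covariate p-value is uniform under the null", {
  # 200 simulated datasets with sex assigned independently of all effects.
  # The check runs on the unstandardized envelope: within-participant
  # standardization removes the between-participant variance a level-2
  # covariate could explain, so on standardized data its p is conservative
  # by construction rather than uniform.
  set.seed(79)
  pvals <- numeric(200)
  for (i in seq_len(200)) {
    cfg <- exp1_config(seed = 1000 + i, n_participants = 15,
                       trials = tiny_trials(2, 30))
    ps <- simulate_paired_series(cfg, standardize = FALSE)
    d <- paired_from_series(ps, "zm")
    pids <- unique(d$participant)
    sex <- stats::setNames(sample(rep(c("f", "m"), length.out = length(pids))),
                           pids)
    out <- sex_covariate_sensitivity(d, sex, direction = "positive")
    pvals[i] <- out$covariate_p
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("translating the valence scale changes only the intercept", {
  ps <- simulate_paired_series(exp1_config(seed = 13))
  d <- paired_from_series(ps, "cs")
  f1 <- fit_concordance_lmm(d)
  d2 <- d; d2$valence <- d2$valence + 4
  f2 <- fit_concordance_lmm(d2)
  expect_equal(f1$gamma[["valence"]], f2$gamma[["valence"]], tolerance = 1e-6)
  t1 <- slope_t_test(f1, 14, "negative")
  t2 <- slope_t_test(f2, 14, "negative")
  expect_equal(t1$t, t2$t, tolerance = 1e-4)
  expect_equal(t1$p, t2$p, tolerance = 1e-6)
  expect_equal(f2$gamma[["(Intercept)"]],
               f1$gamma[["(Intercept)"]] - 4 * f1$gamma[["valence"]],
               tolerance = 1e-5)
})

test_that("a participant with constant valence contributes with a warning", {
  d <- make_linear_data(m = 4, n = 10, noise = 0.1, seed = 6)
  flat <- tibble::tibble(participant = "p99", valence = rep(5, 10),
                         emg = rnorm(10, 0, 0.1))
  expect_warning(fit_concordance_lmm(dplyr::bind_rows(d, flat)),
                 "constant within participant")
  expect_error(fit_concordance_lmm(
    tibble::tibble(participant = rep(c("a", "b", "c"), each = 5),
                   valence = 5, emg = rnorm(15))),
    "constant within every")
})
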