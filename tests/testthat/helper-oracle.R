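# Independent mixed-model oracle: lme4 ML fit of the same random-slope
# model. The predictor is centered (an equivalent reparameterization that
# the fixed slope and the log-likelihood are invariant to) because these
# fits sit near the boundary (within-participant standardization removes
# most intercept variance) and the uncentered problem is ill-conditioned.
# The optimum is taken over several lme4 starts -- the default, bobyqa,
# and optionally a supplied theta -- keeping lme4's own best deviance, as
# lme4::allFit does for boundary-prone fits.
oracle_lmer <- function(d, start_theta = NULL) {
  testthat::skip_if_not_installed("lme4")
  d$vc <- d$valence - mean(d$valence)
  fits <- list()
  quiet <- function(expr) suppressMessages(suppressWarnings(expr))
  fits$default <- quiet(lme4::lmer(emg ~ vc + (vc | participant), data = d,
                                   REML = FALSE))
  fits$bobyqa <- quiet(lme4::lmer(
    emg ~ vc + (vc | participant), data = d, REML = FALSE,
    control = lme4::lmerControl(optimizer = "bobyqa")))
  if (!is.null(start_theta)) {
    fits$started <- quiet(lme4::lmer(
      emg ~ vc + (vc | participant), data = d, REML = FALSE,
      start = list(theta = start_theta),
      control = lme4::lmerControl(optimizer = "bobyqa")))
  }
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  best <- fits[[which.max(ll)]]
  list(slope = lme4::fixef(best)[["vc"]], loglik = max(ll))
}

# lme4 start on the same scale as the package's log-Cholesky theta
theta_chol <- function(fit) c(exp(fit$theta[1]), fit$theta[2],
                              exp(fit$theta[3]))
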