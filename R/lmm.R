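#' Maximum-likelihood linear mixed model for valence-EMG concordance
#'
#' Fits, by full maximum likelihood (not REML), the two-level model
#' \deqn{y_{ij} = \gamma_{00} + \gamma_{10} x_{ij} + u_{0j} + u_{1j} x_{ij}
#' + \varepsilon_{ij}} with correlated by-participant random intercepts and
#' slopes \eqn{(u_{0j}, u_{1j}) \sim N(0, \Psi)} and residuals
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)}. Optional participant-level
#' covariates enter the fixed part only.
#'
#' The relative random-effect covariance \eqn{\Psi/\sigma^2} is
#' parameterized by its log-Cholesky factor (guaranteeing positive
#' semidefiniteness); the fixed effects and \eqn{\sigma^2} are profiled out
#' of the deviance, which is minimized by quasi-Newton iteration
#' (`nlminb`, relative tolerance 1e-12) from two fixed starting points.
#' Per-participant sufficient statistics make each deviance evaluation
#' O(participants), independent of the number of observations.
#'
#' @param data Data frame of paired 1 Hz observations.
#' @param x,y,group Column names of the valence predictor, EMG response and
#'   participant identifier.
#' @param covariates Optional character vector of participant-level
#'   (level-2) covariate columns, constant within participant.
#' @return An object of class `concordance_model`: fixed effects `gamma`
#'   (intercept, slope, covariates), their covariance `vcov`, random-effect
#'   covariance `psi` (tau00, tau01, tau11), residual variance `sigma2`,
#'   `loglik`, per-participant BLUPs `u`, `converged`, `singular`, counts
#'   `m` (participants) and `n_obs`, and the fitting metadata.
#' @export
fit_concordance_lmm <- function(data, x = "valence", y = "emg",
                                group = "participant", covariates = NULL) {
  df <- as.data.frame(data)[, c(group, x, y, covariates)]
  df <- df[complete.cases(df), , drop = FALSE]
  g <- factor(df[[group]])
  m <- nlevels(g)
  if (m < 3) stop_input("need at least 3 participants (got %d)", m)
  xs <- split(df[[x]], g)
  ys <- split(df[[y]], g)
  if (any(vapply(xs, length, 1L) < 3)) {
    stop_input("every participant needs at least 3 paired observations")
  }
  novar <- vapply(xs, function(v) var(v) == 0, TRUE)
  if (all(novar)) {
    stop_input("the predictor is constant within every participant")
  }
  if (any(novar)) {
    warning(sprintf("predictor constant within participant(s) %s; they inform the intercept only",
                    paste(levels(g)[novar], collapse = ", ")), call. = FALSE)
  }

  # Level-2 covariates: one value per participant appended to the fixed design
  wmat <- NULL
  if (!is.null(covariates)) {
    wmat <- vapply(covariates, function(cv) {
      w <- split(df[[cv]], g)
      rng <- vapply(w, function(v) diff(range(v)), 1)
      if (any(rng > 0)) {
        stop_input("covariate '%s' varies within a participant", cv)
      }
      vapply(w, `[`, 1, i = 1L)
    }, numeric(m))
  }

  # Center the predictor for optimization conditioning only: the model
  # family is invariant under the shift (u0' = u0 + c u1), so the slope,
  # its SE and the likelihood are unchanged; intercept-side quantities are
  # transformed back below.
  xc <- mean(df[[x]])
  xs_c <- lapply(xs, function(v) v - xc)

  st <- lmm_suffstats(xs_c, ys, wmat)
  starts <- list(c(log(0.5), 0, log(0.5)), c(log(0.05), 0, log(0.05)))
  fits <- lapply(starts, function(s) {
    stats::nlminb(s, function(th) lmm_profiled_deviance(th, st)$dev,
                  control = list(rel.tol = 1e-12, iter.max = 500,
                                 eval.max = 1000))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 1, "objective"))]]
  sol <- lmm_profiled_deviance(best$par, st)

  p <- length(sol$beta)
  gamma <- sol$beta
  gamma[1] <- gamma[1] - gamma[2] * xc   # intercept back on the raw scale
  names(gamma) <- c("(Intercept)", x, covariates)
  G <- theta_to_G(best$par)
  singular <- sol$sigma2 < 1e-10 || min(diag(G)) < 1e-10
  # Back-transform covariance quantities: T maps centered to raw basis
  Tm <- diag(p); Tm[1, 2] <- -xc
  psi_c <- sol$sigma2 * G
  Tm2 <- matrix(c(1, 0, -xc, 1), 2, 2)
  psi <- Tm2 %*% psi_c %*% t(Tm2)
  dimnames(psi) <- list(c("intercept", "slope"), c("intercept", "slope"))
  vcov_beta <- Tm %*% (sol$sigma2 * solve(sol$XtViX)) %*% t(Tm)
  dimnames(vcov_beta) <- list(names(gamma), names(gamma))

  # BLUPs: u_j = G Z_j' V*_j^{-1} (y_j - X_j beta), centered basis, mapped back
  u <- matrix(0, m, 2, dimnames = list(levels(g), c("intercept", "slope")))
  beta_c <- sol$beta
  for (j in seq_len(m)) {
    r <- ys[[j]] - beta_c[1] - beta_c[2] * xs_c[[j]]
    if (p > 2) r <- r - drop(wmat[j, , drop = FALSE] %*% beta_c[-(1:2)])
    Ztr <- c(sum(r), sum(xs_c[[j]] * r))
    S <- matrix(c(st$S[j, 1], st$S[j, 2], st$S[j, 2], st$S[j, 3]), 2, 2)
    K <- solve(diag(2) + S %*% G)
    u[j, ] <- drop(Tm2 %*% (G %*% K %*% Ztr))
  }

  # nlminb code 0 and its X/relative-convergence messages are clean stops;
  # "singular convergence" is a flat/boundary optimum: accepted, but the
  # fit is flagged singular. Anything else (iteration limit, false
  # convergence) is a non-converged fit.
  msg <- best$message %||% ""
  at_boundary <- grepl("singular convergence", msg)
  converged <- best$convergence == 0 ||
    grepl("relative convergence|X-convergence", msg) || at_boundary

  out <- list(
    gamma = gamma, vcov = vcov_beta, psi = psi, sigma2 = sol$sigma2,
    loglik = -sol$dev / 2, u = u,
    converged = converged, singular = singular || at_boundary,
    message = best$message, theta = best$par,
    m = m, n_obs = nrow(df), x = x, y = y, group = group,
    covariates = covariates,
    groups = levels(g)
  )
  class(out) <- "concordance_model"
  out
}

# Lower-triangular Cholesky factor of the relative covariance G = Psi/sigma^2
# from theta = (log l11, l21, log l22).
theta_to_G <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  L %*% t(L)
}

# Per-participant sufficient statistics for the profiled deviance.
# Columns of A_j = [1, x_j, w_j..., y_j]; stores C_j = A_j'A_j rows for the
# random-effect design Z_j = [1, x_j] plus the accumulated C.
lmm_suffstats <- function(xs, ys, wmat) {
  m <- length(xs)
  p_cov <- if (is.null(wmat)) 0L else ncol(wmat)
  q <- 2L + p_cov + 1L   # columns of A: 1, x, covariates, y
  Csum <- matrix(0, q, q)
  Z1 <- matrix(0, m, q)  # row j: (Z_j' A_j)[1, ] = column sums of A_j
  Z2 <- matrix(0, m, q)  # row j: (Z_j' A_j)[2, ] = x-weighted column sums
  S <- matrix(0, m, 3)   # (n_j, sum x, sum x^2)
  for (j in seq_len(m)) {
    A <- cbind(1, xs[[j]],
               if (p_cov) matrix(rep(wmat[j, ], each = length(xs[[j]])),
                                 ncol = p_cov),
               ys[[j]])
    C <- crossprod(A)
    Csum <- Csum + C
    Z1[j, ] <- C[1, ]
    Z2[j, ] <- C[2, ]
    S[j, ] <- c(C[1, 1], C[1, 2], C[2, 2])
  }
  list(Csum = Csum, Z1 = Z1, Z2 = Z2, S = S, q = q,
       N = sum(vapply(xs, length, 1L)), m = m)
}

# Profiled -2 log-likelihood at theta: GLS fixed effects and sigma^2 are
# closed-form given the relative covariance G. Uses the Woodbury identity
# a'V*^{-1}b = a'b - (Z'a)' G(I + Z'Z G)^{-1} (Z'b), vectorized over
# participants via 2x2 closed forms.
lmm_profiled_deviance <- function(theta, st) {
  G <- theta_to_G(theta)
  g11 <- G[1, 1]; g12 <- G[1, 2]; g22 <- G[2, 2]
  s11 <- st$S[, 1]; s12 <- st$S[, 2]; s22 <- st$S[, 3]
  m11 <- 1 + s11 * g11 + s12 * g12
  m12 <- s11 * g12 + s12 * g22
  m21 <- s12 * g11 + s22 * g12
  m22 <- 1 + s12 * g12 + s22 * g22
  det <- m11 * m22 - m12 * m21
  if (any(det <= 0) || any(!is.finite(det))) return(list(dev = Inf))
  # GK = G (I + S G)^{-1}, symmetric; closed-form 2x2, vectorized over groups
  k11 <- (g11 * m22 - g12 * m21) / det
  k22 <- (g22 * m11 - g12 * m12) / det
  k12 <- ((g12 * m11 - g11 * m12) + (g12 * m22 - g22 * m21)) / (2 * det)
  M <- st$Csum -
    (crossprod(st$Z1, st$Z1 * k11) +
       crossprod(st$Z1, st$Z2 * k12) +
       crossprod(st$Z2, st$Z1 * k12) +
       crossprod(st$Z2, st$Z2 * k22))
  q <- st$q
  XtViX <- M[1:(q - 1), 1:(q - 1), drop = FALSE]
  XtViy <- M[1:(q - 1), q]
  ytViy <- M[q, q]
  beta <- tryCatch(solve(XtViX, XtViy), error = function(e) NULL)
  if (is.null(beta)) return(list(dev = Inf))
  rss <- ytViy - sum(beta * XtViy)
  sigma2 <- max(rss / st$N, .Machine$double.eps)
  dev <- st$N * log(2 * pi * sigma2) + sum(log(det)) + st$N
  list(dev = dev, beta = beta, sigma2 = sigma2, XtViX = XtViX)
}

#' @export
print.concordance_model <- function(x, ...) {
  cat("Linear mixed-effects concordance model (ML)\n")
  cat(sprintf("  %d participants, %d observations\n", x$m, x$n_obs))
  cat("  Fixed effects:\n")
  print(round(x$gamma, 5))
  cat(sprintf("  Random effects SD: intercept %.4f, slope %.4f (cor %.3f)\n",
              sqrt(x$psi[1, 1]), sqrt(x$psi[2, 2]),
              x$psi[1, 2] / sqrt(x$psi[1, 1] * x$psi[2, 2] + 1e-300)))
  cat(sprintf("  Residual SD: %.4f   logLik: %.3f\n",
              sqrt(x$sigma2), x$loglik))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (x$singular) cat("  Note: fit is singular (a variance is at the boundary)\n")
  invisible(x)
}

#' Degrees of freedom by the m - l - 1 approximation
#'
#' Degrees of freedom for testing a level-1 slope in a two-level model:
#' the number of level-2 units (participants) minus the number of level-2
#' predictors minus one.
#'
#' @param m Number of participants (level-2 units).
#' @param l Number of level-2 (participant-level) predictors.
#' @return `m - l - 1`.
#' @export
df_m_l_1 <- function(m, l = 0) {
  if (m <= l + 1) {
    stop_input("m - l - 1 requires m >= l + 2 (got m = %d, l = %d)", m, l)
  }
  m - l - 1
}

#' One-tailed t-test of the concordance slope
#'
#' Tests the fixed slope \eqn{\gamma_{10}} against zero with
#' `t = slope / SE` (SE from the ML information matrix) on a t
#' distribution with externally supplied degrees of freedom (the
#' m - l - 1 rule), one-tailed in the direction hypothesized a priori:
#' negative for the corrugator (frowning), positive for the zygomatic
#' (smiling).
#'
#' @param model A converged [fit_concordance_lmm()] fit.
#' @param df Degrees of freedom (see [df_m_l_1()]).
#' @param direction `"negative"` or `"positive"`: the predicted sign.
#' @param term Name of the tested fixed-effect term (default: the slope).
#' @return Object of class `concordance_test`: `beta`, `se`, `t`, `df`,
#'   `p` (one-tailed), `direction`.
#' @export
slope_t_test <- function(model, df, direction = c("negative", "positive"),
                         term = NULL) {
  direction <- match.arg(direction)
  if (!isTRUE(model$converged)) {
    stop_input("model did not converge; refusing to test (%s)",
               model$message %||% "no diagnostic message")
  }
  term <- term %||% model$x
  beta <- unname(model$gamma[term])
  se <- sqrt(model$vcov[term, term])
  tval <- beta / se
  p <- if (direction == "negative") pt(tval, df) else
    pt(tval, df, lower.tail = FALSE)
  out <- list(beta = beta, se = se, t = tval, df = df, p = p,
              direction = direction, term = term)
  class(out) <- "concordance_test"
  out
}

#' @export
print.concordance_test <- function(x, ...) {
  cat(sprintf("slope %s = %.4f (SE %.4f), t(%d) = %.3f, one-tailed (%s) p = %.4g\n",
              x$term, x$beta, x$se, x$df, x$t, x$direction, x$p))
  invisible(x)
}

#' Standardized residuals of a concordance model
#'
#' Conditional residuals (response minus fixed part minus predicted random
#' part) divided by the estimated residual SD; `type = "marginal"` instead
#' divides the marginal residual by its model-implied per-observation SD.
#'
#' @param model A [fit_concordance_lmm()] fit.
#' @param data The data the model was fitted to.
#' @param type `"conditional"` (default) or `"marginal"`.
#' @return Numeric vector aligned with the complete-case rows of `data`.
#' @export
standardized_residuals <- function(model, data,
                                   type = c("conditional", "marginal")) {
  type <- match.arg(type)
  df <- as.data.frame(data)[, c(model$group, model$x, model$y,
                                model$covariates)]
  df <- df[complete.cases(df), , drop = FALSE]
  g <- factor(df[[model$group]], levels = model$groups)
  xv <- df[[model$x]]
  fixed <- model$gamma[1] + model$gamma[2] * xv
  if (length(model$gamma) > 2) {
    for (i in seq_along(model$covariates)) {
      fixed <- fixed + model$gamma[2 + i] * df[[model$covariates[i]]]
    }
  }
  marg <- df[[model$y]] - fixed
  if (type == "conditional") {
    ui <- model$u[as.integer(g), , drop = FALSE]
    unname((marg - ui[, 1] - ui[, 2] * xv) / sqrt(model$sigma2))
  } else {
    vii <- model$sigma2 +
      model$psi[1, 1] + 2 * model$psi[1, 2] * xv + model$psi[2, 2] * xv^2
    marg / sqrt(vii)
  }
}

#' Flag outlying observations by standardized residual
#'
#' @param residuals Standardized residuals.
#' @param threshold Absolute threshold in SD units (3 by convention).
#' @return Integer indices of observations with |residual| > threshold.
#' @export
flag_outliers <- function(residuals, threshold = 3) {
  which(abs(residuals) > threshold)
}

#' Refit the concordance model after removing residual outliers
#'
#' Recomputes standardized residuals, removes observations beyond the
#' threshold, refits by ML on the remainder, and re-tests the slope with
#' the *same* m - l - 1 degrees of freedom (the participant count is
#' unchanged). If removal would leave a participant with fewer than 3
#' observations, that participant is retained and a warning is issued.
#'
#' @param model A converged fit.
#' @param data The fitted data.
#' @param threshold Outlier threshold in SD units.
#' @param direction Tail direction for the refitted slope test.
#' @param type Residual type passed to [standardized_residuals()].
#' @return List: `test` (refitted [slope_t_test()]), `model` (refit),
#'   `outlier_idx`, `outlier_pct` (percentage of observations removed).
#' @export
refit_without_outliers <- function(model, data, threshold = 3,
                                   direction = c("negative", "positive"),
                                   type = "conditional") {
  direction <- match.arg(direction)
  df <- as.data.frame(data)[, c(model$group, model$x, model$y,
                                model$covariates)]
  df <- df[complete.cases(df), , drop = FALSE]
  res <- standardized_residuals(model, df, type = type)
  idx <- flag_outliers(res, threshold)
  pct <- 100 * length(idx) / nrow(df)
  keep <- df
  if (length(idx)) {
    cand <- df[-idx, , drop = FALSE]
    tab <- table(factor(cand[[model$group]], levels = model$groups))
    if (any(tab < 3)) {
      short <- names(tab)[tab < 3]
      warning(sprintf("outlier removal would leave participant(s) %s with < 3 observations; their outliers are retained",
                      paste(short, collapse = ", ")), call. = FALSE)
      drop_idx <- idx[!df[[model$group]][idx] %in% short]
      cand <- if (length(drop_idx)) df[-drop_idx, , drop = FALSE] else df
    }
    keep <- cand
  }
  refit <- fit_concordance_lmm(keep, x = model$x, y = model$y,
                               group = model$group,
                               covariates = model$covariates)
  test <- slope_t_test(refit, df_m_l_1(model$m, length(model$covariates %||% c())),
                       direction = direction)
  list(test = test, model = refit, outlier_idx = idx, outlier_pct = pct)
}
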