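#' Pearson correlation between aligned 1 Hz series at zero lag
#'
#' @param x,y Aligned 1 Hz numeric series (equal length); missing values
#'   are dropped pairwise.
#' @return Pearson r, or `NA` when either series is constant or fewer than
#'   3 complete pairs remain.
#' @export
zero_lag_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Cross-correlation of two 1 Hz series over integer-second lags
#'
#' Computes the Pearson correlation over the overlapping support at each
#' lag in `-max_lag_s:max_lag_s`. A positive lag means `y` trails `x` by
#' that many seconds (i.e. `x[t]` is paired with `y[t + lag]`).
#'
#' @param x,y Aligned 1 Hz numeric series.
#' @param max_lag_s Maximum absolute lag in seconds.
#' @return Tibble `lag_s, r` (`NA` where undefined).
#' @export
cross_correlation <- function(x, y, max_lag_s) {
  n <- min(length(x), length(y))
  lags <- -max_lag_s:max_lag_s
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      xi <- x[seq_len(n - l)]; yi <- y[seq_len(n - l) + l]
    } else {
      xi <- x[seq_len(n + l) - l]; yi <- y[seq_len(n + l)]
    }
    zero_lag_correlation(xi, yi)
  }, numeric(1))
  tibble::tibble(lag_s = lags, r = r)
}

#' Group-mean concordance summary (scatter + regression line)
#'
#' Averages the EMG response across participants at each trial time point
#' and fits an ordinary least-squares line of the group-mean EMG on the
#' group-mean valence, the group-level summary used for scatterplot
#' figures.
#'
#' @param data Paired observations with columns `trial_id`, `t_s`, plus
#'   the valence and EMG columns.
#' @param x,y Column names of valence and EMG.
#' @return List: `table` (tibble `trial_id, t_s, mean_x, mean_y, n`) and
#'   `coef` (named vector: intercept, slope of the group-mean regression).
#' @export
group_summary <- function(data, x = "valence", y = "emg") {
  d <- tibble::as_tibble(data)
  tab <- dplyr::summarise(
    dplyr::group_by(d, .data$trial_id, .data$t_s),
    mean_x = mean(.data[[x]], na.rm = TRUE),
    mean_y = mean(.data[[y]], na.rm = TRUE),
    n = sum(stats::complete.cases(.data[[x]], .data[[y]])),
    .groups = "drop"
  )
  fit <- lm(mean_y ~ mean_x, data = tab)
  list(table = tab, coef = c(intercept = unname(coef(fit)[1]),
                             slope = unname(coef(fit)[2])))
}

#' Sensitivity of the concordance slope to a sex covariate
#'
#' Refits the concordance model with a binary participant-level covariate
#' added to the fixed part (degrees of freedom drop to m - 1 - 1) and
#' reports whether the original slope's one-tailed significance is
#' unchanged, along with the covariate's two-tailed p value.
#'
#' @param data Paired observations (see [fit_concordance_lmm()]).
#' @param sex Named vector (names = participant ids) or two-column data
#'   frame mapping participant to a two-level sex code.
#' @param direction Tail direction for the slope test.
#' @param alpha Significance level for the "unchanged" comparison.
#' @param x,y,group Column names as in [fit_concordance_lmm()].
#' @return List: `base_test`, `adjusted_test` (slope tests without/with
#'   the covariate), `covariate_p` (two-tailed), `significance_unchanged`.
#' @export
sex_covariate_sensitivity <- function(data, sex,
                                      direction = c("negative", "positive"),
                                      alpha = 0.05,
                                      x = "valence", y = "emg",
                                      group = "participant") {
  direction <- match.arg(direction)
  d <- as.data.frame(data)
  if (is.data.frame(sex)) {
    sx <- stats::setNames(sex[[2]], sex[[1]])
  } else sx <- sex
  lev <- unique(sx[!is.na(sx)])
  if (length(lev) < 2) stop_input("sex covariate has a single level; cannot adjust")
  d$.sex <- as.numeric(factor(sx[as.character(d[[group]])], levels = lev)) - 1
  base <- fit_concordance_lmm(d, x = x, y = y, group = group)
  adj <- fit_concordance_lmm(d, x = x, y = y, group = group,
                             covariates = ".sex")
  m <- base$m
  base_test <- slope_t_test(base, df_m_l_1(m, 0), direction = direction)
  adj_test <- slope_t_test(adj, df_m_l_1(m, 1), direction = direction)
  t_cov <- unname(adj$gamma[".sex"] / sqrt(adj$vcov[".sex", ".sex"]))
  p_cov <- 2 * pt(-abs(t_cov), df_m_l_1(m, 1))
  list(base_test = base_test, adjusted_test = adj_test,
       covariate_t = t_cov, covariate_p = p_cov,
       significance_unchanged =
         (base_test$p < alpha) == (adj_test$p < alpha))
}

#' Build a concordance results table across devices and muscles
#'
#' For every device x muscle cell: fits the mixed model, performs the
#' one-tailed slope test with m - l - 1 degrees of freedom in the a-priori
#' direction (corrugator negative, zygomatic positive by default),
#' computes the standardized-residual outlier percentage, and refits
#' without outliers.
#'
#' @param paired Tibble with columns `participant, device, muscle, trial_id,
#'   t_s, valence, emg`.
#' @param directions Named vector of tail directions per muscle.
#' @param outlier_sd Outlier threshold in SD units.
#' @return Tibble `device, muscle, beta, se, t, df, p_one_tailed,
#'   outlier_pct, beta_refit, t_refit, p_refit`.
#' @export
concordance_table <- function(paired,
                              directions = c(cs = "negative", zm = "positive"),
                              outlier_sd = 3) {
  cells <- unique(paired[, c("device", "muscle")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- paired[paired$device == cells$device[i] &
                  paired$muscle == cells$muscle[i], ]
    dir <- directions[[cells$muscle[i]]]
    fit <- fit_concordance_lmm(d)
    dfree <- df_m_l_1(fit$m, 0)
    test <- slope_t_test(fit, dfree, direction = dir)
    ref <- refit_without_outliers(fit, d, threshold = outlier_sd,
                                  direction = dir)
    tibble::tibble(
      device = cells$device[i], muscle = cells$muscle[i],
      beta = test$beta, se = test$se, t = test$t, df = dfree,
      p_one_tailed = test$p, outlier_pct = ref$outlier_pct,
      beta_refit = ref$test$beta, t_refit = ref$test$t,
      p_refit = ref$test$p
    )
  })
  dplyr::bind_rows(rows)
}

#' Figure end point covering a fraction of variable-length trials
#'
#' Largest whole second `e` such that at least `coverage` of the trial
#' durations reach `e` (used to truncate grand-mean time-course summaries
#' when trials have variable length).
#'
#' @param durations_s Trial durations in seconds.
#' @param coverage Required fraction of trials, default 0.9.
#' @return Integer end point in seconds.
#' @export
coverage_endpoint <- function(durations_s, coverage = 0.9) {
  e <- floor(sort(durations_s))
  cand <- seq_len(max(e))
  frac <- vapply(cand, function(s) mean(e >= s), numeric(1))
  max(cand[frac >= coverage])
}
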