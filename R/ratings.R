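#' One-sample t-test of ratings against the neutral midpoint
#'
#' Tests whether ratings on the nine-point scale differ from the neutral
#' state (5), two-tailed, with a Bonferroni correction for the number of
#' tests in the family (the corrected p is clipped at 1).
#'
#' @param values Numeric ratings (one per participant).
#' @param mu0 Null value, default 5 (scale midpoint).
#' @param n_tests Bonferroni family size.
#' @return List: `mean`, `sd`, `t`, `df`, `p_raw` (two-tailed),
#'   `p_bonferroni`, `n`.
#' @export
one_sample_t_vs_neutral <- function(values, mu0 = 5, n_tests = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop_input("need at least 2 ratings (got %d)", n)
  m <- mean(values); s <- sd(values)
  if (s == 0) {
    if (m == mu0) {
      return(list(mean = m, sd = 0, t = 0, df = n - 1, p_raw = 1,
                  p_bonferroni = 1, n = n))
    }
    stop_input("zero variance with mean %g != %g: t is undefined", m, mu0)
  }
  tval <- (m - mu0) / (s / sqrt(n))
  p <- 2 * pt(-abs(tval), n - 1)
  list(mean = m, sd = s, t = tval, df = n - 1, p_raw = p,
       p_bonferroni = min(1, p * n_tests), n = n)
}

#' Validate cued-recall against on-line continuous ratings
#'
#' For each participant x condition pair, computes the Pearson correlation
#' between the on-line and cued-recall 1 Hz traces; then, per condition,
#' summarizes the correlations (mean, SD) and tests them against zero with
#' Bonferroni-corrected two-tailed one-sample t-tests. Pairs with a
#' constant trace have an undefined correlation and are excluded (counted
#' in `n_dropped`).
#'
#' @param online,recall Tibbles `participant, condition, t_s, valence`
#'   with paired traces of equal length per participant x condition.
#' @param n_tests Bonferroni family size (default: number of conditions).
#' @return List: `per_pair` (tibble `participant, condition, r`),
#'   `per_condition` (tibble `condition, mean_r, sd_r, t, df, p_raw,
#'   p_bonferroni, n`), `n_dropped`.
#' @export
recall_validation <- function(online, recall, n_tests = NULL) {
  key <- c("participant", "condition", "t_s")
  d <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(online), v_online = "valence"),
    dplyr::rename(tibble::as_tibble(recall), v_recall = "valence"),
    by = intersect(names(online), c(key, "trial_id"))
  )
  per_pair <- dplyr::summarise(
    dplyr::group_by(d, .data$participant, .data$condition),
    r = zero_lag_correlation(.data$v_online, .data$v_recall),
    .groups = "drop"
  )
  n_dropped <- sum(is.na(per_pair$r))
  if (n_dropped > 0) {
    message(sprintf("%d pair(s) with a constant trace: correlation undefined, excluded",
                    n_dropped))
  }
  conds <- unique(per_pair$condition)
  n_tests <- n_tests %||% length(conds)
  per_condition <- dplyr::bind_rows(lapply(conds, function(cc) {
    rr <- per_pair$r[per_pair$condition == cc & !is.na(per_pair$r)]
    if (length(rr) >= 2 && sd(rr) == 0 && mean(rr) != 0) {
      # degenerate limit (e.g. recall identical to on-line: all r = 1)
      return(tibble::tibble(condition = cc, mean_r = mean(rr), sd_r = 0,
                            t = sign(mean(rr)) * Inf, df = length(rr) - 1,
                            p_raw = 0, p_bonferroni = 0, n = length(rr)))
    }
    ts <- one_sample_t_vs_neutral(rr, mu0 = 0, n_tests = n_tests)
    tibble::tibble(condition = cc, mean_r = ts$mean, sd_r = ts$sd,
                   t = ts$t, df = ts$df, p_raw = ts$p_raw,
                   p_bonferroni = ts$p_bonferroni, n = ts$n)
  }))
  list(per_pair = per_pair, per_condition = per_condition,
       n_dropped = n_dropped)
}

#' Power of the one-sample t-test
#'
#' Exact power under a noncentral t distribution with noncentrality
#' \eqn{d\sqrt{n}} and `n - 1` degrees of freedom.
#'
#' @param n Sample size (>= 2).
#' @param d Standardized effect size (Cohen's d).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power in \[0, 1\].
#' @export
one_sample_t_power <- function(n, d, alpha = 0.05, tails = 1) {
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 1) {
    pt(qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
}

#' Minimal sample size for a one-sample t-test
#'
#' Smallest `n` whose one-sample t-test power under a noncentral t with
#' noncentrality \eqn{d\sqrt{n}} reaches the target, found by direct
#' integer search (exact at this scale, no normal approximation).
#'
#' @param effect_size_d Standardized effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @param n_max Upper search bound.
#' @return Minimal integer `n`.
#' @export
required_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.80,
                                 tails = 1, n_max = 1000) {
  if (effect_size_d <= 0) stop_input("effect_size_d must be > 0")
  for (n in 2:n_max) {
    if (one_sample_t_power(n, effect_size_d, alpha, tails) >= power) return(n)
  }
  stop_input("no n <= %d reaches power %g for d = %g", n_max, power,
             effect_size_d)
}
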