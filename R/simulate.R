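#' Simulate a latent continuous valence trace
#'
#' Generates a smooth, bounded, mean-reverting 1 Hz valence trajectory as a
#' discretized Ornstein-Uhlenbeck (AR(1)) process around `mean`, clipped to
#' the nine-point rating range \[1, 9\]. The lag-1 autocorrelation of the
#' unclipped process is `exp(-1 / smoothness_s)`.
#'
#' @param duration_s Trace duration in seconds (>= 1); the trace has
#'   `floor(duration_s)` samples, one per second.
#' @param smoothness_s Correlation time of the process in seconds (> 0).
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param mean Stationary mean on the 1-9 scale.
#' @param sd Stationary SD before clipping; `sd = 0` gives a constant trace.
#' @param clip If `FALSE`, return the unclipped latent process.
#' @return Numeric vector of 1 Hz valence values.
#' @export
simulate_valence_trace <- function(duration_s, smoothness_s, seed = NULL,
                                   mean = 5, sd = 1.5, clip = TRUE) {
  if (!is.finite(duration_s) || duration_s < 1) {
    stop_input("duration_s must be a positive duration of at least 1 s")
  }
  if (smoothness_s <= 0) stop_input("smoothness_s must be > 0")
  if (sd < 0) stop_input("sd must be >= 0")
  n <- floor(duration_s)
  with_seed(seed, {
    if (sd == 0) return(rep(mean, n))
    phi <- exp(-1 / smoothness_s)
    dev <- numeric(n)
    dev[1] <- rnorm(1, 0, sd)
    innov <- rnorm(n - 1L, 0, sd * sqrt(1 - phi^2))
    if (n > 1) for (t in 2:n) dev[t] <- phi * dev[t - 1L] + innov[t - 1L]
    x <- mean + dev
    if (clip) x <- pmin(.VALENCE_MAX, pmax(.VALENCE_MIN, x))
    x
  })
}

#' Simulate a cued-recall version of an on-line valence trace
#'
#' Produces a trace that tracks the input (lightly smoothed, as recall of a
#' re-presented stimulus would be) with added independent noise calibrated
#' so the expected Pearson correlation with the original is about
#' `fidelity`.
#'
#' @param trace On-line 1 Hz valence trace.
#' @param fidelity Target correlation with the original, in (0, 1\].
#' @param seed Optional integer seed.
#' @return A 1 Hz valence trace of the same length, clipped to \[1, 9\].
#' @export
simulate_recall_trace <- function(trace, fidelity = 0.8, seed = NULL) {
  if (fidelity <= 0 || fidelity > 1) stop_input("fidelity must lie in (0, 1]")
  n <- length(trace)
  with_seed(seed, {
    dev <- trace - .VALENCE_NEUTRAL
    sm <- as.numeric(stats::filter(dev, rep(1 / 3, 3), sides = 2))
    sm[is.na(sm)] <- dev[is.na(sm)]
    s <- sd(sm)
    noise_sd <- if (s > 0) s * sqrt(1 / fidelity^2 - 1) else 0.5
    out <- .VALENCE_NEUTRAL + sm + rnorm(n, 0, noise_sd)
    pmin(.VALENCE_MAX, pmax(.VALENCE_MIN, out))
  })
}

# Band-limited unit-variance Gaussian carrier in [low, high] Hz.
# The upper edge is truncated below the Nyquist frequency.
emg_carrier <- function(n, fs, low = 20, high = 400) {
  high_tr <- min(high, 0.98 * fs / 2)
  if (fs / 2 <= low || high_tr <= low) {
    stop_input("sampling rate %g Hz is too low for a carrier band starting at %g Hz",
               fs, low)
  }
  bf <- signal::butter(4, c(low, high_tr) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, rnorm(n)))
  x / sd(x)
}

# Slow baseline wander: low-passed random walk rescaled to a target SD (uV).
emg_drift <- function(n, fs, amplitude_uv, corner_hz) {
  if (amplitude_uv <= 0) return(numeric(n))
  bf <- signal::butter(2, min(corner_hz, 0.45 * fs) / (fs / 2), type = "low")
  d <- as.numeric(signal::filter(bf, cumsum(rnorm(n))))
  s <- sd(d)
  if (s == 0) return(numeric(n))
  d / s * amplitude_uv
}

# Map the 1 Hz standardized-scale envelope to a per-sample uV amplitude.
# softplus keeps the amplitude positive while staying linear over the
# operating range (offset 3 puts typical envelopes on the linear part).
envelope_to_amplitude <- function(env_z, fs, n, amp_scale_uv) {
  amp_1hz <- amp_scale_uv * softplus(env_z + 3)
  approx(x = seq_along(env_z) - 0.5, y = amp_1hz,
         xout = (seq_len(n) - 0.5) / fs, rule = 2)$y
}

#' Simulate one raw EMG channel for a single trial
#'
#' Synthesizes surface EMG as amplitude-modulated band-limited (20-400 Hz,
#' truncated below Nyquist) Gaussian noise. The instantaneous amplitude is a
#' softplus-floored linear function of the centered valence trace with the
#' participant's realized slope and intercept; optional slow drift and
#' broadband artifact bursts are added. An optional pre-stimulus baseline
#' segment is generated with the valence term set to zero.
#'
#' @param valence 1 Hz valence trace covering the stimulus window.
#' @param muscle `"cs"` or `"zm"` (selects the coupling sign from `cfg`).
#' @param cfg A [sim_config()].
#' @param participant_effects Numeric `c(intercept = ..., slope = ...)`:
#'   this participant's realized random deviations are already folded in
#'   (i.e. intercept \eqn{u_{0j}} and total slope \eqn{\gamma_{10}+u_{1j}}).
#' @param seed Optional integer seed.
#' @param device Device label (must be in `cfg$devices`); sets the rate.
#' @param baseline_s Length of the leading baseline segment in seconds.
#' @param artifact_intervals Optional data frame with `artifact_start_s`,
#'   `artifact_end_s` (relative to the start of the returned channel).
#' @return List with `samples_uv`, `fs`, `device`, `muscle`, `t0 = 0`.
#' @export
simulate_emg <- function(valence, muscle = c("cs", "zm"), cfg,
                         participant_effects = c(intercept = 0, slope = NA),
                         seed = NULL, device = names(cfg$devices)[1],
                         baseline_s = 0, artifact_intervals = NULL) {
  muscle <- match.arg(muscle)
  if (!device %in% names(cfg$devices)) {
    stop_input("unknown device '%s'", device)
  }
  fs <- unname(cfg$devices[[device]])
  slope <- participant_effects[["slope"]]
  if (is.na(slope)) slope <- unname(cfg$coupling[[muscle]])
  u0 <- participant_effects[["intercept"]]
  with_seed(seed, {
    n_bl <- floor(baseline_s)
    env_z <- c(rep(u0, n_bl), u0 + slope * (valence - .VALENCE_NEUTRAL)) +
      rnorm(n_bl + length(valence), 0, cfg$noise_sd)
    n <- (n_bl + length(valence)) * fs
    amp <- envelope_to_amplitude(env_z, fs, n, cfg$amp_scale_uv)
    x <- amp * emg_carrier(n, fs) +
      emg_drift(n, fs, cfg$drift_amplitude_uv, cfg$drift_corner_hz)
    x <- add_artifact_bursts(x, fs, artifact_intervals, cfg$amp_scale_uv)
    list(samples_uv = x, fs = fs, device = device, muscle = muscle, t0 = 0)
  })
}

# High-amplitude broadband transients inside annotated intervals (times in
# seconds relative to the start of `x`).
add_artifact_bursts <- function(x, fs, intervals, amp_scale_uv) {
  if (is.null(intervals) || nrow(intervals) == 0) return(x)
  n <- length(x)
  for (k in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor(intervals$artifact_start_s[k] * fs) + 1L)
    i1 <- min(n, floor(intervals$artifact_end_s[k] * fs))
    if (i1 < i0) next
    m <- i1 - i0 + 1L
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
    x[i0:i1] <- x[i0:i1] + taper * rnorm(m, 0, 12 * amp_scale_uv)
  }
  x
}

# Draw per-participant random intercept/slope deviations for one muscle.
draw_participant_effects <- function(n, intercept_sd, slope_sd, re_cor) {
  u0 <- rnorm(n, 0, intercept_sd)
  u1 <- re_cor * (slope_sd / max(intercept_sd, 1e-12)) * u0 +
    rnorm(n, 0, slope_sd * sqrt(1 - re_cor^2))
  if (intercept_sd == 0) u1 <- rnorm(n, 0, slope_sd)
  tibble::tibble(intercept = u0, slope = u1)
}

# Build the per-participant trial layout (absolute times on the recording).
layout_trials <- function(cfg) {
  if (!is.null(cfg$trials)) {
    tr <- cfg$trials
  } else {
    fr <- cfg$frames
    durs <- numeric(0)
    while (sum(durs) < fr$session_s) {
      d <- rnorm(1, fr$mean_s, fr$sd_s)
      if (d >= fr$min_s) durs <- c(durs, d)
    }
    tr <- tibble::tibble(duration_s = durs,
                         condition = "game",
                         mu_valence = fr$mu_valence,
                         has_baseline = FALSE)
  }
  pad <- 3
  t <- pad
  rows <- vector("list", nrow(tr))
  for (k in seq_len(nrow(tr))) {
    has_bl <- isTRUE(tr$has_baseline[k])
    bl_start <- if (has_bl) t else NA_real_
    stim_start <- if (has_bl) t + cfg$baseline_s else t
    stim_end <- stim_start + floor(tr$duration_s[k])
    rows[[k]] <- tibble::tibble(
      trial_id = k, condition = tr$condition[k], mu_valence = tr$mu_valence[k],
      baseline_start_s = bl_start, stim_start_s = stim_start,
      stim_end_s = stim_end
    )
    t <- stim_end + cfg$gap_s
  }
  list(events = dplyr::bind_rows(rows), total_s = t - cfg$gap_s + pad)
}

# Poisson artifact bursts inside each trial's stimulus window.
draw_artifacts <- function(events, cfg) {
  if (cfg$artifact_rate_per_min <= 0) {
    return(tibble::tibble(trial_id = integer(), artifact_start_s = numeric(),
                          artifact_end_s = numeric()))
  }
  out <- list()
  for (k in seq_len(nrow(events))) {
    dur <- events$stim_end_s[k] - events$stim_start_s[k]
    n_art <- rpois(1, cfg$artifact_rate_per_min * dur / 60)
    if (n_art == 0) next
    span <- dur - cfg$artifact_duration_s
    if (span <= 0) next
    starts <- sort(runif(n_art, 0, span)) + events$stim_start_s[k]
    out[[length(out) + 1L]] <- tibble::tibble(
      trial_id = events$trial_id[k],
      artifact_start_s = starts,
      artifact_end_s = pmin(starts + cfg$artifact_duration_s,
                            events$stim_end_s[k])
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(trial_id = integer(), artifact_start_s = numeric(),
                          artifact_end_s = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Simulate a complete synthetic experiment
#'
#' Generates, for every participant, the latent valence trace of each trial,
#' raw two-channel EMG for every configured device, per-trial overall
#' ratings, event and artifact tables, and the ground truth needed for
#' parameter-recovery checks (realized per-participant slopes/intercepts and
#' the noiseless coupled envelope). Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()] (see [exp1_config()], [exp2_config()]).
#' @param raw If `FALSE`, skip raw EMG synthesis (events, traces, ratings
#'   and ground truth only) for fast statistical studies.
#' @return A list of class `emg_dataset` with elements `config`,
#'   `recordings` (named `"<participant>.<device>"`), `events`, `artifacts`,
#'   `traces`, `ratings_overall` and `ground_truth`.
#' @export
simulate_experiment <- function(cfg, raw = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    pids <- sprintf("p%02d", seq_len(cfg$n_participants))
    effects <- dplyr::bind_rows(lapply(c("cs", "zm"), function(mu) {
      eff <- draw_participant_effects(cfg$n_participants, cfg$intercept_sd,
                                      cfg$slope_sd, cfg$re_cor)
      tibble::tibble(participant = pids, muscle = mu,
                     intercept = eff$intercept,
                     slope = unname(cfg$coupling[[mu]]) + eff$slope)
    }))

    recordings <- list()
    all_events <- list(); all_art <- list(); all_traces <- list()
    all_ratings <- list()

    for (i in seq_len(cfg$n_participants)) {
      pid <- pids[i]
      lay <- layout_trials(cfg)
      ev <- lay$events
      art <- draw_artifacts(ev, cfg)
      n_env <- ceiling(lay$total_s)

      traces <- lapply(seq_len(nrow(ev)), function(k) {
        simulate_valence_trace(ev$stim_end_s[k] - ev$stim_start_s[k],
                               cfg$valence_smoothness_s,
                               mean = ev$mu_valence[k], sd = cfg$valence_sd)
      })
      all_traces[[pid]] <- dplyr::bind_rows(lapply(seq_along(traces), function(k) {
        tibble::tibble(participant = pid, trial_id = ev$trial_id[k],
                       condition = ev$condition[k],
                       t_s = seq_along(traces[[k]]) - 1L,
                       valence = traces[[k]])
      }))

      # 1 Hz standardized-scale envelope over the whole recording, per muscle
      env <- lapply(c("cs", "zm"), function(mu) {
        eff <- effects[effects$participant == pid & effects$muscle == mu, ]
        e <- rep(eff$intercept, n_env)
        for (k in seq_len(nrow(ev))) {
          sec <- floor(ev$stim_start_s[k]) + seq_along(traces[[k]])
          e[sec] <- eff$intercept +
            eff$slope * (traces[[k]] - .VALENCE_NEUTRAL)
        }
        e + rnorm(n_env, 0, cfg$noise_sd)
      })
      names(env) <- c("cs", "zm")

      if (raw) {
        for (dev in names(cfg$devices)) {
          fs <- unname(cfg$devices[[dev]])
          n <- n_env * fs
          chans <- lapply(c("cs", "zm"), function(mu) {
            amp <- envelope_to_amplitude(env[[mu]], fs, n, cfg$amp_scale_uv)
            x <- amp * emg_carrier(n, fs) +
              emg_drift(n, fs, cfg$drift_amplitude_uv, cfg$drift_corner_hz)
            add_artifact_bursts(x, fs, art, cfg$amp_scale_uv)
          })
          names(chans) <- c("cs", "zm")
          recordings[[paste(pid, dev, sep = ".")]] <- list(
            participant = pid, device = dev, fs = fs, t0 = 0,
            samples = chans
          )
        }
      }

      # Overall ratings consistent with each trial's realized valence
      all_ratings[[pid]] <- dplyr::bind_rows(lapply(seq_len(nrow(ev)), function(k) {
        v <- round(mean(traces[[k]]) + rnorm(1, 0, 0.7))
        a <- if (!is.null(cfg$trials) && "mu_arousal" %in% names(cfg$trials)) {
          round(cfg$trials$mu_arousal[k] + rnorm(1, 0, 1))
        } else NA_real_
        tibble::tibble(participant = pid, trial_id = ev$trial_id[k],
                       condition = ev$condition[k],
                       valence = min(.VALENCE_MAX, max(.VALENCE_MIN, v)),
                       arousal = if (is.na(a)) NA_real_ else
                         min(.VALENCE_MAX, max(.VALENCE_MIN, a)))
      }))

      ev$participant <- pid
      all_events[[pid]] <- ev[, c("participant", "trial_id", "condition",
                                  "baseline_start_s", "stim_start_s",
                                  "stim_end_s")]
      if (nrow(art)) {
        art$participant <- pid
        all_art[[pid]] <- art[, c("participant", "trial_id",
                                  "artifact_start_s", "artifact_end_s")]
      }
    }

    traces_tbl <- dplyr::bind_rows(all_traces)
    noiseless <- dplyr::left_join(traces_tbl,
                                  tidyr::pivot_wider(effects,
                                                     names_from = "muscle",
                                                     values_from = c("intercept", "slope")),
                                  by = "participant")
    noiseless <- dplyr::transmute(
      noiseless,
      participant = .data$participant, trial_id = .data$trial_id,
      t_s = .data$t_s,
      cs = .data$slope_cs * (.data$valence - .VALENCE_NEUTRAL),
      zm = .data$slope_zm * (.data$valence - .VALENCE_NEUTRAL)
    )

    out <- list(
      config = cfg,
      recordings = recordings,
      events = dplyr::bind_rows(all_events),
      artifacts = if (length(all_art)) dplyr::bind_rows(all_art) else
        tibble::tibble(participant = character(), trial_id = integer(),
                       artifact_start_s = numeric(), artifact_end_s = numeric()),
      traces = traces_tbl,
      ratings_overall = dplyr::bind_rows(all_ratings),
      ground_truth = list(effects = effects, noiseless_envelope = noiseless)
    )
    class(out) <- "emg_dataset"
    out
  })
}

#' Simulate paired valence-envelope series at the 1 Hz envelope level
#'
#' Fast path for statistical studies: skips raw-EMG carrier synthesis and
#' returns, per muscle, the 1 Hz envelope each participant would contribute
#' after preprocessing but before within-individual standardization:
#' \eqn{y_{jt} = u_{0j} + (\gamma_{10} + u_{1j})(x_{jt} - 5) +
#' \varepsilon_{jt}}. Statistical structure (random effects, residual noise,
#' valence process) is identical to the raw-path generator.
#'
#' @param cfg A [sim_config()].
#' @param standardize If `TRUE` (default), z-score the envelope within each
#'   participant over the concatenated trials, as the analysis pipeline
#'   does.
#' @return List with `data` (tibble: participant, trial_id, condition, t_s,
#'   valence, cs, zm) and `effects` (realized per-participant coefficients).
#' @export
simulate_paired_series <- function(cfg, standardize = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    pids <- sprintf("p%02d", seq_len(cfg$n_participants))
    effects <- dplyr::bind_rows(lapply(c("cs", "zm"), function(mu) {
      eff <- draw_participant_effects(cfg$n_participants, cfg$intercept_sd,
                                      cfg$slope_sd, cfg$re_cor)
      tibble::tibble(participant = pids, muscle = mu,
                     intercept = eff$intercept,
                     slope = unname(cfg$coupling[[mu]]) + eff$slope)
    }))
    rows <- vector("list", cfg$n_participants)
    for (i in seq_len(cfg$n_participants)) {
      pid <- pids[i]
      lay <- layout_trials(cfg)
      ev <- lay$events
      per_tr <- lapply(seq_len(nrow(ev)), function(k) {
        v <- simulate_valence_trace(ev$stim_end_s[k] - ev$stim_start_s[k],
                                    cfg$valence_smoothness_s,
                                    mean = ev$mu_valence[k],
                                    sd = cfg$valence_sd)
        tibble::tibble(participant = pid, trial_id = ev$trial_id[k],
                       condition = ev$condition[k],
                       t_s = seq_along(v) - 1L, valence = v)
      })
      d <- dplyr::bind_rows(per_tr)
      for (mu in c("cs", "zm")) {
        eff <- effects[effects$participant == pid & effects$muscle == mu, ]
        y <- eff$intercept + eff$slope * (d$valence - .VALENCE_NEUTRAL) +
          rnorm(nrow(d), 0, cfg$noise_sd)
        if (standardize) y <- as.numeric(scale(y))
        d[[mu]] <- y
      }
      rows[[i]] <- d
    }
    list(data = dplyr::bind_rows(rows), effects = effects)
  })
}
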