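#' Simulation configuration for a synthetic EMG-valence experiment
#'
#' Bundles every parameter of the synthetic-data generator: the participant
#' and trial layout, the per-device sampling rates, the fixed
#' envelope-valence coupling per muscle (on the standardized envelope scale,
#' i.e. z-units per valence-scale unit), the between-participant random
#' effect structure, residual envelope noise, slow drift, artifact bursts,
#' and the latent valence process.
#'
#' @param n_participants Number of participants (>= 1).
#' @param trials Either a data frame with columns `duration_s`, `condition`,
#'   `mu_valence` and `has_baseline` describing a fixed trial list shared by
#'   all participants (film-viewing layout), or `NULL` when `frames` is used.
#' @param frames `NULL`, or a list with elements `mean_s`, `sd_s`, `min_s`,
#'   `session_s` and `mu_valence` describing variable-length game frames
#'   drawn per participant until the session length is covered (no
#'   baselines).
#' @param devices Named numeric vector of sampling rates in Hz; names are
#'   device labels, values must be 1000 (wired) or 500 (wearable).
#' @param coupling Named numeric vector `c(cs = ..., zm = ...)`: fixed
#'   population slope of the standardized envelope on the 1-9 valence
#'   rating. Defaults follow the usual facial-EMG directions: negative for
#'   corrugator supercilii (frowning), positive for zygomatic major
#'   (smiling).
#' @param intercept_sd,slope_sd SDs of by-participant random intercepts and
#'   slopes around the fixed effects (z-units, z per valence unit).
#' @param re_cor Correlation between random intercept and slope, in (-1, 1).
#' @param noise_sd Residual 1 Hz envelope noise SD (z-units).
#' @param drift_amplitude_uv SD of the additive slow baseline wander, in uV.
#' @param drift_corner_hz Low-pass corner of the drift process, in Hz.
#' @param artifact_rate_per_min Expected number of artifact bursts per
#'   minute of stimulus time (annotated in the event table).
#' @param artifact_duration_s Duration of each artifact burst, seconds.
#' @param valence_smoothness_s Correlation time of the latent
#'   Ornstein-Uhlenbeck valence process, seconds.
#' @param valence_sd Stationary SD of the latent valence process
#'   (valence-scale units, before clipping to \[1, 9\]).
#' @param amp_scale_uv Overall raw-EMG amplitude scale in uV; downstream
#'   results are invariant to it (within-individual standardization).
#' @param baseline_s Pre-stimulus baseline window length, seconds (used only
#'   for trials with `has_baseline = TRUE`).
#' @param gap_s Inter-trial gap, seconds.
#' @param seed Integer seed making the whole dataset reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [exp1_config()], [exp2_config()], [simulate_experiment()]
#' @export
sim_config <- function(n_participants,
                       trials = NULL,
                       frames = NULL,
                       devices = c(wired = 1000, wearable = 500),
                       coupling = c(cs = -0.2, zm = 0.15),
                       intercept_sd = 0.3,
                       slope_sd = 0.1,
                       re_cor = 0,
                       noise_sd = 0.95,
                       drift_amplitude_uv = 20,
                       drift_corner_hz = 0.5,
                       artifact_rate_per_min = 0,
                       artifact_duration_s = 2,
                       valence_smoothness_s = 20,
                       valence_sd = 1.5,
                       amp_scale_uv = 4,
                       baseline_s = 10,
                       gap_s = 6,
                       seed = 1L) {
  if (n_participants < 1) stop_input("n_participants must be >= 1")
  if (is.null(trials) == is.null(frames)) {
    stop_input("exactly one of `trials` or `frames` must be given")
  }
  if (!is.null(trials)) {
    need <- c("duration_s", "condition", "mu_valence", "has_baseline")
    if (!all(need %in% names(trials))) {
      stop_input("`trials` must have columns %s", paste(need, collapse = ", "))
    }
    if (any(trials$duration_s < 1)) stop_input("trial durations must be >= 1 s")
  }
  if (!all(devices %in% c(1000, 500))) {
    stop_input("device sampling rates must be 1000 (wired) or 500 (wearable) Hz")
  }
  if (is.null(names(devices)) || any(!nzchar(names(devices)))) {
    stop_input("`devices` must be a named vector of sampling rates")
  }
  if (!all(c("cs", "zm") %in% names(coupling))) {
    stop_input("`coupling` must name both muscles: cs, zm")
  }
  nonneg <- c(intercept_sd = intercept_sd, slope_sd = slope_sd,
              noise_sd = noise_sd, drift_amplitude_uv = drift_amplitude_uv,
              artifact_rate_per_min = artifact_rate_per_min,
              artifact_duration_s = artifact_duration_s,
              valence_sd = valence_sd, baseline_s = baseline_s, gap_s = gap_s)
  if (any(nonneg < 0)) {
    stop_input("negative value for %s",
               paste(names(nonneg)[nonneg < 0], collapse = ", "))
  }
  if (valence_smoothness_s <= 0) stop_input("valence_smoothness_s must be > 0")
  if (drift_corner_hz <= 0) stop_input("drift_corner_hz must be > 0")
  if (abs(re_cor) >= 1) stop_input("re_cor must lie in (-1, 1)")
  cfg <- list(
    n_participants = as.integer(n_participants),
    trials = if (!is.null(trials)) tibble::as_tibble(trials),
    frames = frames,
    devices = devices,
    coupling = coupling[c("cs", "zm")],
    intercept_sd = intercept_sd, slope_sd = slope_sd, re_cor = re_cor,
    noise_sd = noise_sd,
    drift_amplitude_uv = drift_amplitude_uv, drift_corner_hz = drift_corner_hz,
    artifact_rate_per_min = artifact_rate_per_min,
    artifact_duration_s = artifact_duration_s,
    valence_smoothness_s = valence_smoothness_s, valence_sd = valence_sd,
    amp_scale_uv = amp_scale_uv,
    baseline_s = baseline_s, gap_s = gap_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Film-viewing experiment preset (wired + wearable devices)
#'
#' Fifteen participants view five emotional films (138-205 s, mean 173.4 s)
#' spanning highly negative to highly positive valence, each preceded by a
#' 10-s pre-stimulus baseline, while EMG is recorded simultaneously with a
#' wired device at 1000 Hz and a wearable device at 500 Hz.
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
exp1_config <- function(n_participants = 15, seed = 1L, ...) {
  trials <- tibble::tibble(
    duration_s   = c(205, 160, 138, 172, 192),
    condition    = c("anger", "sadness", "neutral", "contentment", "amusement"),
    mu_valence   = c(2.3, 3.2, 5.0, 6.3, 7.2),
    mu_arousal   = c(6.8, 5.5, 2.5, 4.5, 6.5),
    has_baseline = TRUE
  )
  args <- list(n_participants = n_participants, trials = trials, seed = seed,
               devices = c(wired = 1000, wearable = 500),
               coupling = c(cs = -0.2, zm = 0.15),
               slope_sd = 0.1, artifact_rate_per_min = 0)
  ov <- list(...)
  args[names(ov)] <- ov   # replace whole components (no element-wise merge)
  do.call(sim_config, args)
}

#' Motion-game experiment preset (wearable device only)
#'
#' Twenty-three participants play a bowling video game for about ten
#' minutes; each frame (mean 26.7 s, SD 8.9 s) is a trial with no
#' pre-stimulus baseline. Movement artifacts occur at a rate chosen so that
#' roughly 6.5% of stimulus time is annotated for excision. Only the
#' wearable 500 Hz device records.
#'
#' @inheritParams exp1_config
#' @return A `sim_config`.
#' @export
exp2_config <- function(n_participants = 23, seed = 1L, ...) {
  frames <- list(mean_s = 26.7, sd_s = 8.9, min_s = 8, session_s = 570,
                 mu_valence = 6)
  args <- list(n_participants = n_participants, frames = frames, seed = seed,
               devices = c(wearable = 500),
               coupling = c(cs = -0.03, zm = 0.03),
               slope_sd = 0.05,
               artifact_rate_per_min = 2, artifact_duration_s = 2,
               baseline_s = 0)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}
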