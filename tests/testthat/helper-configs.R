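# Small generator configurations used across tests: short trials and few
# participants keep raw-EMG synthesis fast while preserving the full
# statistical structure (random slopes/intercepts, OU valence, drift).

tiny_trials <- function(n_trials = 2, duration_s = 40, has_baseline = TRUE) {
  tibble::tibble(
    duration_s = rep(duration_s, n_trials),
    condition = paste0("cond", seq_len(n_trials)),
    mu_valence = seq(3, 7, length.out = n_trials),
    has_baseline = has_baseline
  )
}

tiny_exp1_cfg <- function(seed = 1, n = 4, ...) {
  sim_config(n_participants = n, trials = tiny_trials(), seed = seed,
             devices = c(wired = 1000, wearable = 500),
             coupling = c(cs = -0.3, zm = 0.3), ...)
}

tiny_exp2_cfg <- function(seed = 1, n = 4, ...) {
  sim_config(n_participants = n,
             frames = list(mean_s = 15, sd_s = 4, min_s = 6, session_s = 60,
                           mu_valence = 6),
             devices = c(wearable = 500),
             coupling = c(cs = -0.3, zm = 0.3),
             artifact_rate_per_min = 4, artifact_duration_s = 2,
             baseline_s = 0, seed = seed, ...)
}

# Paired valence/EMG observations for one muscle from an envelope-level
# simulation (the shape fit_concordance_lmm() expects).
paired_from_series <- function(ps, muscle = "cs") {
  d <- ps$data
  tibble::tibble(participant = d$participant, trial_id = d$trial_id,
                 t_s = d$t_s, valence = d$valence, emg = d[[muscle]])
}
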