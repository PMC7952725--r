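#' Zero-phase high-pass (low-cut) filter
#'
#' Applies a Butterworth high-pass filter forward and backward
#' (zero-phase), so envelope timing is not shifted relative to the rating
#' trace. The 20 Hz low-cut is the standard facial-EMG choice for removing
#' motion-related artifacts.
#'
#' @param x Numeric signal in uV.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order (the effective order doubles with the
#'   forward-backward pass).
#' @return Filtered signal, same length as `x`.
#' @export
highpass_filter <- function(x, fs, cutoff = 20, order = 4) {
  if (cutoff >= fs / 2) {
    stop_input("cutoff %g Hz is not below the Nyquist frequency %g Hz",
               cutoff, fs / 2)
  }
  if (length(x) < 3 * order) stop_input("signal too short for the filter order")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Subtract a centered moving average (baseline-drift removal)
#'
#' Removes slow baseline wander by subtracting from each sample the mean of
#' a centered window (51 points by default, i.e. ~102 ms at 500 Hz). At the
#' edges the window shrinks symmetrically-truncated to the available
#' samples, so the output has the same length as the input.
#'
#' @param x Numeric signal.
#' @param window Odd window length in samples.
#' @return `x` minus its centered running mean.
#' @export
subtract_moving_average <- function(x, window = 51) {
  if (window %% 2 == 0) stop_input("window must be odd (got %d)", window)
  n <- length(x)
  if (n < window) stop_input("signal shorter than the moving-average window")
  h <- (window - 1) / 2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, n)
  x - (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Full-wave rectification
#'
#' @param x Numeric signal.
#' @return Elementwise absolute value.
#' @export
rectify <- function(x) abs(x)

#' Epoch a rectified signal and average into fixed-length bins
#'
#' Cuts the (already rectified) signal into per-trial stimulus windows,
#' averages it in consecutive `bin_ms` bins aligned to stimulus onset, and
#' computes the mean over the pre-stimulus baseline window when one is
#' annotated. A trailing partial bin is dropped. Samples inside annotated
#' artifact intervals are excluded before averaging; a bin with more than
#' 50% of its samples excluded is marked missing (`NA`).
#'
#' @param x Rectified signal.
#' @param fs Sampling rate in Hz.
#' @param events Data frame with one row per trial: `trial_id`, `condition`,
#'   `baseline_start_s` (may be `NA`), `stim_start_s`, `stim_end_s`. Times
#'   are seconds from the start of `x`.
#' @param artifacts Optional data frame `trial_id`, `artifact_start_s`,
#'   `artifact_end_s` (absolute seconds, within the stimulus window).
#' @param bin_ms Bin length in milliseconds.
#' @return List with `bins`, a tibble `trial_id, condition, t_bin_s, value,
#'   missing`, and `baselines`, a tibble `trial_id, baseline_mean` (`NA`
#'   when no baseline window is annotated).
#' @export
epoch_and_bin <- function(x, fs, events, artifacts = NULL, bin_ms = 1000) {
  n <- length(x)
  bin_len <- round(fs * bin_ms / 1000)
  if (bin_len < 1) stop_input("bin_ms too small for sampling rate %g", fs)
  bins_out <- list(); bl_out <- list()
  for (k in seq_len(nrow(events))) {
    tid <- events$trial_id[k]
    t0 <- events$stim_start_s[k]; t1 <- events$stim_end_s[k]
    i0 <- floor(t0 * fs + 1e-9)
    i1 <- floor(t1 * fs + 1e-9)
    if (i0 < 0 || i1 > n) {
      stop_input("trial %s: stimulus window [%g, %g] s lies outside the recording",
                 tid, t0, t1)
    }
    nbins <- floor((i1 - i0) / bin_len)
    if (nbins == 0) {
      stop_input("trial %s: stimulus window shorter than one bin", tid)
    }
    idx <- i0 + seq_len(nbins * bin_len)
    keep <- rep(TRUE, length(idx))
    if (!is.null(artifacts) && nrow(artifacts)) {
      arts <- artifacts[artifacts$trial_id == tid, , drop = FALSE]
      for (a in seq_len(nrow(arts))) {
        j0 <- floor(arts$artifact_start_s[a] * fs + 1e-9) + 1L
        j1 <- floor(arts$artifact_end_s[a] * fs + 1e-9)
        sel <- idx >= j0 & idx <= j1
        keep[sel] <- FALSE
      }
    }
    seg <- x[idx]
    bid <- rep(seq_len(nbins), each = bin_len)
    sums <- rowsum(seg * keep, bid)
    cnts <- rowsum(as.numeric(keep), bid)
    val <- as.numeric(sums / cnts)
    miss <- as.numeric(cnts) < bin_len / 2
    val[miss] <- NA_real_
    bins_out[[k]] <- tibble::tibble(
      trial_id = tid, condition = events$condition[k],
      t_bin_s = seq_len(nbins) - 1L, value = val, missing = miss
    )
    bl <- NA_real_
    if (!is.na(events$baseline_start_s[k])) {
      b0 <- floor(events$baseline_start_s[k] * fs + 1e-9)
      b1 <- i0
      if (b0 < 0 || b1 > n || b1 <= b0) {
        stop_input("trial %s: baseline window lies outside the recording", tid)
      }
      bl <- mean(x[(b0 + 1L):b1])
    }
    bl_out[[k]] <- tibble::tibble(trial_id = tid, baseline_mean = bl)
  }
  list(bins = dplyr::bind_rows(bins_out), baselines = dplyr::bind_rows(bl_out))
}

#' Baseline-correct binned values against the pre-stimulus mean
#'
#' Subtracts each trial's pre-stimulus baseline mean from its binned
#' values (film-viewing mode). In game mode (`mode = "none"`) the values
#' pass through unchanged, since free play has no clean rest window.
#'
#' @param bins Tibble from [epoch_and_bin()] (`$bins`).
#' @param baselines Tibble from [epoch_and_bin()] (`$baselines`).
#' @param mode `"baseline"` to subtract, `"none"` to bypass.
#' @return `bins` with corrected `value`.
#' @export
baseline_correct <- function(bins, baselines, mode = c("baseline", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(bins)
  if (anyNA(baselines$baseline_mean)) {
    bad <- baselines$trial_id[is.na(baselines$baseline_mean)]
    stop_input("baseline correction requested but trial(s) %s have no baseline window",
               paste(bad, collapse = ", "))
  }
  out <- dplyr::left_join(bins, baselines, by = "trial_id")
  out$value <- out$value - out$baseline_mean
  out$baseline_mean <- NULL
  out
}

#' Standardize binned values within an individual
#'
#' Concatenates all of one participant's trials (one muscle, one device)
#' and z-scores the values over the concatenation using the sample (n - 1)
#' SD. Missing bins are excluded from the mean/SD and stay missing.
#'
#' @param trials List of numeric vectors (one per trial; `NA` = missing
#'   bin), or a single numeric vector.
#' @return Input structure with standardized values (mean 0, SD 1 over the
#'   concatenated non-missing bins).
#' @export
standardize_within_individual <- function(trials) {
  single <- !is.list(trials)
  if (single) trials <- list(trials)
  all_v <- unlist(trials, use.names = FALSE)
  ok <- !is.na(all_v)
  if (sum(ok) < 2) stop_input("need at least 2 non-missing bins to standardize")
  m <- mean(all_v[ok]); s <- sd(all_v[ok])
  if (s == 0) stop_input("zero variance: cannot standardize this individual")
  out <- lapply(trials, function(v) (v - m) / s)
  if (single) out[[1]] else out
}

#' Preprocess one raw recording into 1 Hz binned envelopes
#'
#' Device-specific conditioning followed by envelope extraction for both
#' channels of a recording: zero-phase 20 Hz high-pass; for the wearable
#' device additionally the 51-point moving-average subtraction; then
#' rectification and 1-s binning per trial with artifact excision.
#'
#' @param recording List with `samples` (named list `cs`, `zm` of uV
#'   vectors), `fs`, `device`, `participant`.
#' @param events This participant's event rows (see [epoch_and_bin()]).
#' @param artifacts This participant's artifact rows (or `NULL`).
#' @param bin_ms Bin length in ms.
#' @param filter_spec List with `cutoff` (Hz) and `order`.
#' @param ma_window Moving-average window (samples) for the wearable path.
#' @return Long tibble `participant, device, muscle, trial_id, condition,
#'   t_bin_s, value, missing, baseline_mean`.
#' @export
preprocess_recording <- function(recording, events, artifacts = NULL,
                                 bin_ms = 1000,
                                 filter_spec = list(cutoff = 20, order = 4),
                                 ma_window = 51) {
  out <- list()
  for (mu in names(recording$samples)) {
    x <- highpass_filter(recording$samples[[mu]], recording$fs,
                         cutoff = filter_spec$cutoff,
                         order = filter_spec$order)
    if (identical(recording$device, "wearable")) {
      x <- subtract_moving_average(x, ma_window)
    }
    x <- rectify(x)
    eb <- epoch_and_bin(x, recording$fs, events, artifacts, bin_ms)
    b <- dplyr::left_join(eb$bins, eb$baselines, by = "trial_id")
    b$participant <- recording$participant
    b$device <- recording$device
    b$muscle <- mu
    out[[mu]] <- b
  }
  dplyr::bind_rows(out)[, c("participant", "device", "muscle", "trial_id",
                            "condition", "t_bin_s", "value", "missing",
                            "baseline_mean")]
}

#' Run the full preprocessing pipeline over a dataset
#'
#' Applies [preprocess_recording()] to every recording, baseline-corrects
#' when the experiment has pre-stimulus windows, and standardizes the
#' concatenated trials within each participant x device x muscle.
#'
#' @param dataset An `emg_dataset` from [simulate_experiment()] or
#'   [read_dataset()].
#' @param bin_ms Bin length in ms.
#' @param filter_spec List with `cutoff` and `order` for the high-pass.
#' @return Tidy tibble `participant, device, muscle, trial_id, condition,
#'   t_bin_s, value_z, missing_flag`.
#' @export
preprocess_dataset <- function(dataset, bin_ms = 1000,
                               filter_spec = list(cutoff = 20, order = 4)) {
  has_baseline <- any(!is.na(dataset$events$baseline_start_s))
  rows <- lapply(dataset$recordings, function(rec) {
    ev <- dataset$events[dataset$events$participant == rec$participant, ]
    art <- dataset$artifacts[dataset$artifacts$participant == rec$participant, ]
    b <- preprocess_recording(rec, ev, art, bin_ms, filter_spec)
    if (has_baseline) {
      b$value <- b$value - b$baseline_mean
    }
    b
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$participant, .data$device, .data$muscle)
  out <- dplyr::mutate(
    out,
    value_z = (.data$value - mean(.data$value, na.rm = TRUE)) /
      sd(.data$value, na.rm = TRUE)
  )
  out <- dplyr::ungroup(out)
  dplyr::select(out, "participant", "device", "muscle", "trial_id",
                "condition", "t_bin_s", value_z = "value_z",
                missing_flag = "missing")
}
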