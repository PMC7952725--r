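#' Assemble a reproducible run configuration
#'
#' Bundles the experiment preset, simulation configuration and analysis
#' switches into a single serializable object; a run is reproducible from
#' the persisted configuration and seed alone.
#'
#' @param preset `"exp1"` (film viewing, wired + wearable) or `"exp2"`
#'   (motion game, wearable only).
#' @param seed Integer seed.
#' @param outdir Output directory for all run products.
#' @param outlier_sd Standardized-residual outlier threshold.
#' @param bin_ms Envelope bin length in ms.
#' @param directions Named tail directions per muscle.
#' @param ... Simulation overrides forwarded to [exp1_config()] /
#'   [exp2_config()].
#' @return List of class `run_config`.
#' @export
run_config <- function(preset = c("exp1", "exp2"), seed = 1L,
                       outdir = tempfile("emgvalence_run_"),
                       outlier_sd = 3, bin_ms = 1000,
                       directions = c(cs = "negative", zm = "positive"),
                       ...) {
  preset <- match.arg(preset)
  sim <- if (preset == "exp1") exp1_config(seed = seed, ...) else
    exp2_config(seed = seed, ...)
  cfg <- list(preset = preset, seed = as.integer(seed), outdir = outdir,
              outlier_sd = outlier_sd, bin_ms = bin_ms,
              directions = directions, sim = sim)
  class(cfg) <- "run_config"
  cfg
}

save_run_config <- function(config, path) {
  sim <- unclass(config$sim)
  sim$devices <- as.list(sim$devices)     # keep names through JSON
  sim$coupling <- as.list(sim$coupling)
  ser <- list(preset = config$preset, seed = config$seed,
              outlier_sd = config$outlier_sd, bin_ms = config$bin_ms,
              directions = as.list(config$directions),
              sim = sim)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Restore a run configuration persisted by [run_simulate()]
#'
#' @param path Path to a `run_config.json`.
#' @param outdir Optional new output directory.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, outdir = dirname(path)) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- j$sim
  sim_args$trials <- if (!is.null(sim_args$trials))
    tibble::as_tibble(sim_args$trials)
  sim_args$devices <- unlist(sim_args$devices)
  sim_args$coupling <- unlist(sim_args$coupling)
  sim <- do.call(sim_config, sim_args)
  cfg <- list(preset = j$preset, seed = j$seed, outdir = outdir,
              outlier_sd = j$outlier_sd, bin_ms = j$bin_ms,
              directions = unlist(j$directions), sim = sim)
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a dataset and persist it with its configuration
#'
#' @param config A [run_config()].
#' @return The dataset directory path, invisibly.
#' @export
run_simulate <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$outdir)) {
    stop_input("cannot create output directory '%s'", config$outdir)
  }
  sim <- simulate_experiment(config$sim)
  ds_dir <- file.path(config$outdir, "dataset")
  write_dataset(sim, ds_dir)
  save_run_config(config, file.path(config$outdir, "run_config.json"))
  invisible(ds_dir)
}

#' Preprocess a persisted (or in-memory) dataset
#'
#' @param config A [run_config()].
#' @param dataset Optional in-memory `emg_dataset`; when `NULL` the
#'   persisted dataset under `config$outdir` is read.
#' @return The tidy preprocessed tibble (also written to
#'   `processed.csv` with a JSON processing log).
#' @export
run_preprocess <- function(config, dataset = NULL) {
  if (is.null(dataset)) {
    ds_dir <- file.path(config$outdir, "dataset")
    if (!dir.exists(ds_dir)) {
      stop_input("no dataset at '%s'; run run_simulate() first", ds_dir)
    }
    dataset <- read_dataset(ds_dir)
  }
  proc <- preprocess_dataset(dataset, bin_ms = config$bin_ms)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(proc, file.path(config$outdir, "processed.csv"))
  jsonlite::write_json(
    list(filter = list(kind = "highpass", cutoff_hz = 20, order = 4,
                       zero_phase = TRUE),
         wearable_moving_average_points = 51,
         bin_ms = config$bin_ms,
         standardization = "within participant x device x muscle, sample SD",
         baseline_correction = any(!is.na(dataset$events$baseline_start_s)),
         missing_bin_rule = "> 50% of samples inside annotated artifacts"),
    file.path(config$outdir, "preprocess_log.json"), auto_unbox = TRUE
  )
  proc
}

# Join preprocessed envelopes with the 1 Hz valence traces.
pair_with_ratings <- function(processed, traces) {
  long <- dplyr::inner_join(
    processed,
    dplyr::select(traces, "participant", "trial_id", t_bin_s = "t_s",
                  "valence"),
    by = c("participant", "trial_id", "t_bin_s")
  )
  long$emg <- long$value_z
  long$emg[long$missing_flag] <- NA_real_
  long$t_s <- long$t_bin_s
  long
}

#' Fit concordance models for every device x muscle cell
#'
#' @param config A [run_config()].
#' @param dataset Optional in-memory dataset (else read from disk).
#' @param processed Optional preprocessed tibble (else recomputed).
#' @return Results tibble from [concordance_table()] (also written to
#'   `concordance_results.csv`).
#' @export
run_fit <- function(config, dataset = NULL, processed = NULL) {
  if (is.null(dataset)) dataset <- read_dataset(file.path(config$outdir, "dataset"))
  if (is.null(processed)) processed <- run_preprocess(config, dataset)
  paired <- pair_with_ratings(processed, dataset$traces)
  res <- concordance_table(paired, directions = config$directions,
                           outlier_sd = config$outlier_sd)
  readr::write_csv(res, file.path(config$outdir, "concordance_results.csv"))
  res
}

#' Analyze overall ratings against the neutral midpoint
#'
#' Film-viewing preset: one test per condition and rating scale (valence
#' and arousal), Bonferroni family of 10. Game preset: one test of the
#' per-participant mean frame valence.
#'
#' @param config A [run_config()].
#' @param dataset Optional in-memory dataset.
#' @return Tibble `condition, scale, mean, sd, t, df, p_raw, p_bonferroni`.
#' @export
run_ratings <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- read_dataset(file.path(config$outdir, "dataset"))
  ro <- dataset$ratings_overall
  if (config$preset == "exp1") {
    conds <- unique(ro$condition)
    scales <- c("valence", if (!all(is.na(ro$arousal))) "arousal")
    n_tests <- length(conds) * length(scales)
    rows <- list()
    for (cc in conds) {
      for (sc in scales) {
        v <- ro[[sc]][ro$condition == cc]
        ts <- one_sample_t_vs_neutral(v, mu0 = 5, n_tests = n_tests)
        rows[[paste(cc, sc)]] <- tibble::tibble(
          condition = cc, scale = sc, mean = ts$mean, sd = ts$sd,
          t = ts$t, df = ts$df, p_raw = ts$p_raw,
          p_bonferroni = ts$p_bonferroni
        )
      }
    }
    out <- dplyr::bind_rows(rows)
  } else {
    pm <- dplyr::summarise(dplyr::group_by(ro, .data$participant),
                           v = mean(.data$valence), .groups = "drop")
    ts <- one_sample_t_vs_neutral(pm$v, mu0 = 5, n_tests = 1)
    out <- tibble::tibble(condition = "game", scale = "valence",
                          mean = ts$mean, sd = ts$sd, t = ts$t, df = ts$df,
                          p_raw = ts$p_raw, p_bonferroni = ts$p_bonferroni)
  }
  readr::write_csv(out, file.path(config$outdir, "rating_results.csv"))
  out
}

# Second-by-second group-mean time course (mean and SE across participants
# and trials); variable-length trials are truncated at the end point
# covering 90% of them.
timecourse_table <- function(paired, dataset) {
  durs <- dataset$events$stim_end_s - dataset$events$stim_start_s
  endpoint <- if (length(unique(round(durs))) > 1) {
    coverage_endpoint(durs, 0.9)
  } else max(floor(durs))
  d <- paired[paired$t_s < endpoint, ]
  dplyr::summarise(
    dplyr::group_by(d, .data$device, .data$muscle, .data$t_s),
    mean_valence = mean(.data$valence, na.rm = TRUE),
    mean_emg = mean(.data$emg, na.rm = TRUE),
    se_emg = sd(.data$emg, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$emg))),
    .groups = "drop"
  )
}

#' Run the complete pipeline: simulate, preprocess, fit, report
#'
#' @param config A [run_config()].
#' @param write_raw If `TRUE`, persist the raw EMG dataset to disk and
#'   re-read it (the fully file-mediated path); if `FALSE`, pass the
#'   simulated dataset through memory (results are identical).
#' @return List: `results` (concordance table), `ratings`, `timecourse`,
#'   `group_summaries` (per device x muscle regression of group means),
#'   `outdir`.
#' @export
run_full <- function(config, write_raw = FALSE) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  save_run_config(config, file.path(config$outdir, "run_config.json"))
  if (write_raw) {
    run_simulate(config)
    dataset <- read_dataset(file.path(config$outdir, "dataset"))
  } else {
    dataset <- simulate_experiment(config$sim)
  }
  processed <- run_preprocess(config, dataset)
  paired <- pair_with_ratings(processed, dataset$traces)
  results <- concordance_table(paired, directions = config$directions,
                               outlier_sd = config$outlier_sd)
  readr::write_csv(results, file.path(config$outdir, "concordance_results.csv"))
  ratings <- run_ratings(config, dataset)
  tc <- timecourse_table(paired, dataset)
  readr::write_csv(tc, file.path(config$outdir, "timecourse.csv"))
  cells <- unique(paired[, c("device", "muscle")])
  gs <- lapply(seq_len(nrow(cells)), function(i) {
    d <- paired[paired$device == cells$device[i] &
                  paired$muscle == cells$muscle[i], ]
    cf <- group_summary(d)$coef
    tibble::tibble(device = cells$device[i], muscle = cells$muscle[i],
                   intercept = cf[["intercept"]], slope = cf[["slope"]])
  })
  list(results = results, ratings = ratings, timecourse = tc,
       group_summaries = dplyr::bind_rows(gs), outdir = config$outdir,
       ground_truth = dataset$ground_truth)
}
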