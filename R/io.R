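#' Write a synthetic dataset to disk
#'
#' Serializes an `emg_dataset` as plain-text files: one delimited raw-EMG
#' file per participant x device (`emg/<participant>_<device>.csv` with
#' columns `time_s, cs_uv, zm_uv`) plus a JSON metadata sidecar; event,
#' artifact and rating tables; and a structured ground-truth JSON.
#'
#' @param dataset An `emg_dataset` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_input("cannot create output directory '%s'", dir)
  emg_dir <- file.path(dir, "emg")
  dir.create(emg_dir, showWarnings = FALSE)
  for (rec in dataset$recordings) {
    stem <- sprintf("%s_%s", rec$participant, rec$device)
    n <- length(rec$samples$cs)
    data.table::fwrite(
      data.table::data.table(
        time_s = round((seq_len(n) - 1) / rec$fs, 6),
        cs_uv = round(rec$samples$cs, 4),
        zm_uv = round(rec$samples$zm, 4)
      ),
      file.path(emg_dir, paste0(stem, ".csv"))
    )
    jsonlite::write_json(
      list(sampling_rate_hz = rec$fs, device = rec$device,
           participant_id = rec$participant, seed = dataset$config$seed),
      file.path(emg_dir, paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_csv(dataset$events, file.path(dir, "events.csv"))
  readr::write_csv(dataset$artifacts, file.path(dir, "artifacts.csv"))
  readr::write_csv(dataset$traces[, c("participant", "trial_id", "condition",
                                      "t_s", "valence")],
                   file.path(dir, "ratings_continuous.csv"))
  readr::write_csv(dataset$ratings_overall, file.path(dir, "ratings_overall.csv"))
  jsonlite::write_json(
    list(effects = dataset$ground_truth$effects,
         seed = dataset$config$seed),
    file.path(dir, "ground_truth.json"), digits = NA, dataframe = "columns"
  )
  invisible(dir)
}

#' Read a synthetic dataset from disk
#'
#' Inverse of [write_dataset()]: reconstructs the recordings (from the
#' delimited EMG files and their JSON sidecars) and the event, artifact and
#' rating tables.
#'
#' @param dir Dataset directory.
#' @return A list of class `emg_dataset` (without the generating config;
#'   `ground_truth` holds the persisted effects table).
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop_input("dataset directory '%s' does not exist", dir)
  emg_files <- list.files(file.path(dir, "emg"), pattern = "\\.csv$",
                          full.names = TRUE)
  recordings <- list()
  for (f in emg_files) {
    meta <- jsonlite::read_json(sub("\\.csv$", ".json", f))
    d <- data.table::fread(f)
    recordings[[sprintf("%s.%s", meta$participant_id, meta$device)]] <- list(
      participant = meta$participant_id, device = meta$device,
      fs = meta$sampling_rate_hz, t0 = 0,
      samples = list(cs = d$cs_uv, zm = d$zm_uv)
    )
  }
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    j <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    list(effects = tibble::as_tibble(j$effects))
  }
  out <- list(
    config = NULL,
    recordings = recordings,
    events = readr::read_csv(file.path(dir, "events.csv"),
                             show_col_types = FALSE),
    artifacts = readr::read_csv(file.path(dir, "artifacts.csv"),
                                show_col_types = FALSE),
    traces = readr::read_csv(file.path(dir, "ratings_continuous.csv"),
                             show_col_types = FALSE),
    ratings_overall = readr::read_csv(file.path(dir, "ratings_overall.csv"),
                                      show_col_types = FALSE),
    ground_truth = gt
  )
  class(out) <- "emg_dataset"
  out
}
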