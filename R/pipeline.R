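#' Preprocess one subject's recording
#'
#' The fixed preprocessing chain: zero-phase 0.3-30 Hz band-pass,
#' response-conditional segmentation with the 11 ms display-offset
#' correction, moving-average artifact detection, bad-channel
#' interpolation, 200 ms pre-stimulus baseline correction, and average
#' re-referencing over scalp channels.
#'
#' @param eeg An [eeg_continuous()].
#' @param events An [event_list()].
#' @param montage The recording montage.
#' @param criteria [artifact_criteria()] (defaults to the study thresholds).
#' @param band Band-pass edges in Hz.
#' @param window_ms,offset_ms Segmentation parameters.
#' @return List with `epochs` (clean, corrected, re-referenced) and
#'   `report` (the [detect_artifacts()] report).
#' @export
preprocess_subject <- function(eeg, events, montage,
                               criteria = artifact_criteria(),
                               band = c(0.3, 30),
                               window_ms = c(-200, 1000), offset_ms = 11) {
  eeg <- bandpass_filter(eeg, band[1], band[2])
  epochs <- segment_epochs(eeg, events, window_ms, offset_ms)
  report <- detect_artifacts(epochs, criteria, montage)
  epochs <- replace_bad_channels(epochs, report, montage)
  epochs <- baseline_correct(epochs)
  epochs <- rereference_average(epochs, montage)
  list(epochs = epochs, report = report)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialisation; identical hashes imply
#' numerically identical reruns.
#'
#' @param config A configuration list.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Simulate a study cohort to disk
#'
#' Writes, under `out_dir`: the montage as JSON, one EDF recording and one
#' events TSV per subject, and the rating tables as CSV. Returns a run
#' configuration consumable by [run_pipeline()].
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param n_channels Montage channel count (default 16).
#' @param paradigm A [paradigm_spec()].
#' @param population A [study_population()].
#' @param ... Passed to [cohort_profiles()] (e.g. `noise_sd`).
#' @return The run configuration list (invisibly written to
#'   `config.json`).
#' @export
simulate_study <- function(n_subjects, seed, out_dir,
                           n_channels = 16,
                           paradigm = paradigm_spec(),
                           population = study_population(), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  montage <- build_montage(n_channels)
  montage_path <- file.path(out_dir, "montage.json")
  write_montage_json(montage, montage_path)

  profiles <- cohort_profiles(n_subjects, seed, population, ...)
  subjects <- data.frame(eeg = character(n_subjects),
                         events = character(n_subjects))
  for (s in seq_len(n_subjects)) {
    rec <- simulate_recording(profiles[[s]], paradigm, montage,
                              seed = seed + s)
    subjects$eeg[s] <- file.path(out_dir, sprintf("sub-%02d_eeg.edf", s))
    subjects$events[s] <- file.path(out_dir, sprintf("sub-%02d_events.tsv", s))
    write_edf(rec$eeg, subjects$eeg[s])
    write_events_tsv(rec$events, subjects$events[s])
  }

  ratings <- simulate_ratings(subject_profile(), n_subjects,
                              seed = seed + n_subjects + 1L)
  ratings_path <- file.path(out_dir, "ratings.csv")
  utils::write.csv(ratings, ratings_path, row.names = FALSE)

  config <- list(montage = montage_path,
                 subjects = subjects,
                 ratings = ratings_path,
                 out_dir = out_dir,
                 band = c(0.3, 30), window_ms = c(-200, 1000),
                 offset_ms = 11, alpha = 0.05, seed = seed)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config)
}

#' Read a pipeline configuration from JSON
#' @param path Path to a `config.json`.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full analysis pipeline from files
#'
#' Executes filter, segment, detect, replace, baseline, re-reference,
#' average, extract and the statistical layer for every configured subject,
#' writing per-subject artifact reports, the long-format amplitude table,
#' a stats JSON bundle and a run log (with the configuration hash) under
#' `config$out_dir`.
#'
#' @param config Configuration list as produced by [simulate_study()] or
#'   [read_config()]; `criteria` may hold [artifact_criteria()] overrides.
#' @return Invisibly, a list with `amplitudes`, `amplitude_stats`,
#'   `rating_stats`, `reports`, `grand_avg`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  montage <- read_montage_json(config$montage)
  criteria <- if (is.null(config$criteria)) artifact_criteria() else
    do.call(artifact_criteria, config$criteria)
  hash <- config_hash(config)

  subjects <- as.data.frame(config$subjects)
  averages <- vector("list", nrow(subjects))
  reports <- vector("list", nrow(subjects))
  for (s in seq_len(nrow(subjects))) {
    eeg <- read_edf(subjects$eeg[s])
    events <- read_events_tsv(subjects$events[s])
    pp <- preprocess_subject(eeg, events, montage, criteria,
                             band = config$band %||% c(0.3, 30),
                             window_ms = config$window_ms %||% c(-200, 1000),
                             offset_ms = config$offset_ms %||% 11)
    reports[[s]] <- pp$report
    averages[[s]] <- subject_average(pp$epochs)
    write_artifact_report_csv(
      pp$report, file.path(out_dir, sprintf("sub-%02d_artifacts.csv", s)))
  }

  if (!any(vapply(averages, function(a) a$complete, logical(1)))) {
    stop("no epochs retained: every subject lost a condition to artifact ",
         "rejection", call. = FALSE)
  }

  amplitudes <- component_table(averages, default_component_windows(),
                                montage)
  write_amplitude_csv(amplitudes, file.path(out_dir, "amplitudes.csv"))
  grand <- grand_average(averages)
  utils::write.csv(waveform_frame(grand),
                   file.path(out_dir, "grand_average_waveforms.csv"),
                   row.names = FALSE)

  alpha <- config$alpha %||% 0.05
  amplitude_stats <- analyze_amplitudes(amplitudes, alpha)
  rating_stats <- NULL
  if (!is.null(config$ratings)) {
    ratings <- utils::read.csv(config$ratings, stringsAsFactors = FALSE)
    rating_stats <- analyze_ratings(ratings, alpha)
  }

  stats_bundle <- list(config_hash = hash,
                       amplitude_stats = amplitude_stats,
                       rating_stats = rating_stats)
  jsonlite::write_json(
    rapply(stats_bundle, unclass, how = "replace"),
    file.path(out_dir, "stats.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")

  log_lines <- c(
    sprintf("erpnat %s", as.character(utils::packageVersion("erpnat"))),
    sprintf("config_hash: %s", hash),
    sprintf("seed: %s", config$seed %||% "none"),
    sprintf("subjects: %d", nrow(subjects)),
    sprintf("rejected epochs: %s",
            paste(vapply(reports, function(r) r$counts$n_rejected,
                         numeric(1)), collapse = " ")),
    sprintf("discordant events dropped per subject: %s",
            paste(vapply(averages, function(a)
              sum(a$n_epochs), numeric(1)), collapse = " ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(amplitudes = amplitudes,
                 amplitude_stats = amplitude_stats,
                 rating_stats = rating_stats,
                 reports = reports, grand_avg = grand,
                 config_hash = hash))
}

#' Simulate and analyse a cohort in memory
#'
#' End-to-end study without file I/O: draws a cohort of subject profiles,
#' simulates and preprocesses each recording, extracts the amplitude
#' table, and runs the statistical layer on amplitudes and simulated
#' ratings. This is the programmatic equivalent of [simulate_study()]
#' followed by [run_pipeline()].
#'
#' @param n_subjects Cohort size (default 27).
#' @param seed Integer seed.
#' @param n_channels Montage size (default 16).
#' @param paradigm,population,criteria Study condition objects.
#' @param ... Passed to [cohort_profiles()].
#' @return List with `profiles`, `amplitudes`, `amplitude_stats`,
#'   `rating_stats`, `averages`, `reports`.
#' @export
run_study <- function(n_subjects = 27, seed = 1, n_channels = 16,
                      paradigm = paradigm_spec(),
                      population = study_population(),
                      criteria = artifact_criteria(), ...) {
  montage <- build_montage(n_channels)
  profiles <- cohort_profiles(n_subjects, seed, population, ...)
  averages <- vector("list", n_subjects)
  reports <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    rec <- simulate_recording(profiles[[s]], paradigm, montage,
                              seed = seed + s)
    pp <- preprocess_subject(rec$eeg, rec$events, montage, criteria)
    averages[[s]] <- subject_average(pp$epochs)
    reports[[s]] <- pp$report
  }
  amplitudes <- component_table(averages, default_component_windows(),
                                montage)
  ratings <- simulate_ratings(subject_profile(), n_subjects,
                              seed = seed + n_subjects + 1L)
  list(profiles = profiles,
       amplitudes = amplitudes,
       amplitude_stats = analyze_amplitudes(amplitudes),
       rating_stats = analyze_ratings(ratings),
       averages = averages, reports = reports)
}
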