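#' Component measurement window
#'
#' Search window and polarity for adaptive-mean amplitude extraction. The
#' defaults are the study's early visual components: P1, a positive
#' deflection measured in 70-130 ms, and N170, a negative deflection in
#' 150-200 ms, both with a 10 ms adaptive-mean halfwidth.
#'
#' @param name `"P1"` or `"N170"`.
#' @param window_ms Search window in ms (start < end).
#' @param polarity `"positive"` or `"negative"`; must match the component
#'   (P1 positive, N170 negative).
#' @param halfwidth_ms Averaging halfwidth around the detected peak.
#' @return An object of class `component_window`.
#' @export
component_window <- function(name = c("P1", "N170"),
                             window_ms = NULL,
                             polarity = NULL,
                             halfwidth_ms = 10) {
  name <- match.arg(name)
  window_ms <- window_ms %||% switch(name, P1 = c(70, 130), N170 = c(150, 200))
  polarity <- polarity %||% switch(name, P1 = "positive", N170 = "negative")
  if (window_ms[1] >= window_ms[2]) {
    stop("window start must precede its end", call. = FALSE)
  }
  expected <- switch(name, P1 = "positive", N170 = "negative")
  if (polarity != expected) {
    stop(sprintf("%s is a %s-going component", name, expected), call. = FALSE)
  }
  if (halfwidth_ms <= 0) stop("`halfwidth_ms` must be > 0", call. = FALSE)
  structure(list(name = name, window_ms = window_ms, polarity = polarity,
                 halfwidth_ms = halfwidth_ms),
            class = "component_window")
}

#' Default P1 and N170 windows
#' @return List of two [component_window()] objects.
#' @export
default_component_windows <- function() {
  list(component_window("P1"), component_window("N170"))
}

#' Per-subject condition averages
#'
#' Arithmetic mean across retained (clean) epochs, per condition, channel
#' and sample. A condition with zero retained epochs marks the subject
#' incomplete; incomplete subjects are excluded from the amplitude table
#' with a log message.
#'
#' @param epochs A cleaned, baseline-corrected, average-referenced
#'   [segment_epochs()] result.
#' @return An object of class `subject_average`: per-condition channel x
#'   sample matrices, epoch counts, times, and a `complete` flag.
#' @export
subject_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- c("human_natural", "ai_unnatural")
  waves <- list()
  n_ep <- c(human_natural = 0L, ai_unnatural = 0L)
  for (cond in conds) {
    sel <- which(epochs$condition == cond & epochs$flags == "clean")
    n_ep[cond] <- length(sel)
    if (length(sel) > 0) {
      waves[[cond]] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
      rownames(waves[[cond]]) <- epochs$channel_labels
    }
  }
  structure(
    list(waveforms = waves, n_epochs = n_ep,
         times_ms = epochs$times_ms,
         sampling_rate_hz = epochs$sampling_rate_hz,
         channel_labels = epochs$channel_labels,
         complete = all(n_ep >= 1L)),
    class = "subject_average"
  )
}

#' @export
print.subject_average <- function(x, ...) {
  cat(sprintf("<subject_average>%s epochs: human_natural=%d ai_unnatural=%d\n",
              if (x$complete) "" else " [incomplete]",
              x$n_epochs[["human_natural"]], x$n_epochs[["ai_unnatural"]]))
  invisible(x)
}

#' Grand average across subjects
#'
#' Unweighted mean of the per-subject average waveforms (every subject
#' contributes equally, regardless of retained epoch count). Incomplete
#' subjects are skipped.
#'
#' @param subject_averages Non-empty list of [subject_average()] results.
#' @return A `subject_average` whose `n_epochs` holds the subject count per
#'   condition.
#' @export
grand_average <- function(subject_averages) {
  subject_averages <- Filter(function(s) s$complete, subject_averages)
  if (length(subject_averages) == 0) {
    stop("no complete subjects to grand-average", call. = FALSE)
  }
  template <- subject_averages[[1]]
  waves <- list()
  n_sub <- c(human_natural = 0L, ai_unnatural = 0L)
  for (cond in c("human_natural", "ai_unnatural")) {
    ws <- lapply(subject_averages, function(s) s$waveforms[[cond]])
    waves[[cond]] <- Reduce(`+`, ws) / length(ws)
    n_sub[cond] <- length(ws)
  }
  structure(
    list(waveforms = waves, n_epochs = n_sub,
         times_ms = template$times_ms,
         sampling_rate_hz = template$sampling_rate_hz,
         channel_labels = template$channel_labels,
         complete = TRUE),
    class = "subject_average"
  )
}

#' Adaptive-mean component amplitude
#'
#' Locates the extremum of the component's polarity within its search
#' window (maximum for positive components, minimum for negative; the
#' earliest sample wins ties) and returns the mean amplitude over
#' peak +/- halfwidth, with the averaging interval clipped to the search
#' window when the peak lies near an edge.
#'
#' @param waveform Numeric single-channel trace.
#' @param window A [component_window()].
#' @param rate_hz Sampling rate in Hz.
#' @param times_ms Optional vector of sample times in ms; defaults to an
#'   epoch starting at -200 ms.
#' @return Amplitude in the trace's units (microvolts).
#' @export
adaptive_mean <- function(waveform, window, rate_hz = 1000, times_ms = NULL) {
  stopifnot(inherits(window, "component_window"))
  times_ms <- times_ms %||% ((seq_along(waveform) - 1) * 1000 / rate_hz - 200)
  sel <- which(times_ms >= window$window_ms[1] &
                 times_ms <= window$window_ms[2])
  if (length(sel) == 0) {
    stop("component window outside the trace", call. = FALSE)
  }
  seg <- waveform[sel]
  peak_rel <- if (window$polarity == "positive") which.max(seg) else
    which.min(seg)                       # which.* take the earliest tie
  peak_t <- times_ms[sel[peak_rel]]
  avg <- which(times_ms >= max(peak_t - window$halfwidth_ms,
                               window$window_ms[1]) &
                 times_ms <= min(peak_t + window$halfwidth_ms,
                                 window$window_ms[2]))
  mean(waveform[avg])
}

#' Per-subject amplitude table
#'
#' Extracts the adaptive-mean amplitude of every component at the
#' text-specific (P7) and face-specific (P8) sites from each subject's
#' condition averages, mapping condition to agent identity
#' (`human_natural` to `human`, `ai_unnatural` to `AI`). Incomplete
#' subjects are omitted with a message.
#'
#' @param subject_averages List of [subject_average()] results.
#' @param windows List of [component_window()]s (default P1 and N170).
#' @param montage Montage providing the P7/P8 labels.
#' @return Long-format `amplitude_table` data.frame: `subject`,
#'   `component`, `identity`, `site`, `amplitude_uv`.
#' @export
component_table <- function(subject_averages,
                            windows = default_component_windows(),
                            montage) {
  stopifnot(inherits(montage, "erp_montage"))
  if (!all(c("P7", "P8") %in% montage$channel_labels)) {
    stop("montage must contain P7 and P8", call. = FALSE)
  }
  cond_of <- c(human = "human_natural", AI = "ai_unnatural")
  rows <- list()
  for (s in seq_along(subject_averages)) {
    sa <- subject_averages[[s]]
    if (!sa$complete) {
      message(sprintf("subject %d incomplete (empty condition); omitted", s))
      next
    }
    for (w in windows) {
      for (id in c("human", "AI")) {
        for (site in c("P7", "P8")) {
          amp <- adaptive_mean(sa$waveforms[[cond_of[[id]]]][site, ], w,
                               sa$sampling_rate_hz, sa$times_ms)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, component = w$name, identity = id, site = site,
            amplitude_uv = amp)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("amplitude_table", "data.frame")
  out
}

#' Write / read an amplitude table as CSV
#' @param table An `amplitude_table`.
#' @param path File path.
#' @export
write_amplitude_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplitude_csv
#' @export
read_amplitude_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("amplitude_table", "data.frame")
  out
}

#' Export waveforms as a long data.frame (for plotting)
#'
#' @param average A [subject_average()] or [grand_average()] result.
#' @param channels Channel labels to include (default P7 and P8).
#' @return data.frame with `condition`, `channel`, `time_ms`, `amplitude_uv`.
#' @export
waveform_frame <- function(average, channels = c("P7", "P8")) {
  stopifnot(inherits(average, "subject_average"))
  rows <- list()
  for (cond in names(average$waveforms)) {
    for (ch in channels) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, channel = ch, time_ms = average$times_ms,
        amplitude_uv = average$waveforms[[cond]][ch, ])
    }
  }
  do.call(rbind, rows)
}
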