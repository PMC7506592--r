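#' Artifact rejection criteria
#'
#' Thresholds of the moving-average max-minus-min artifact rules: a scalp
#' channel is bad within a segment when its smoothed range exceeds
#' `segment_channel_bad_uv`; a segment is rejected when it has more than
#' `max_bad_channels_per_segment` bad channels, a vertical-ocular range
#' above `blink_uv`, or a horizontal-ocular range above `eye_move_uv`; a
#' channel bad in more than `global_bad_channel_fraction` of the segments is
#' marked bad in all of them. Defaults are the study values (200 / 140 / 55
#' microvolts, 80 ms moving average, 10 channels, 20%).
#'
#' @param segment_channel_bad_uv,blink_uv,eye_move_uv Thresholds in
#'   microvolts.
#' @param moving_avg_ms Boxcar length in ms.
#' @param max_bad_channels_per_segment Count above which a segment is
#'   rejected.
#' @param global_bad_channel_fraction Fraction in (0, 1).
#' @param method `"smooth_range"` (smooth with the boxcar, then take the
#'   global max-minus-min; default) or `"windowed_range"` (largest
#'   max-minus-min within any single boxcar-length window).
#' @return An object of class `artifact_criteria`.
#' @export
artifact_criteria <- function(segment_channel_bad_uv = 200,
                              blink_uv = 140,
                              eye_move_uv = 55,
                              moving_avg_ms = 80,
                              max_bad_channels_per_segment = 10,
                              global_bad_channel_fraction = 0.20,
                              method = c("smooth_range", "windowed_range")) {
  thr <- c(segment_channel_bad_uv, blink_uv, eye_move_uv, moving_avg_ms)
  if (any(thr <= 0)) stop("all thresholds must be > 0", call. = FALSE)
  if (global_bad_channel_fraction <= 0 || global_bad_channel_fraction >= 1) {
    stop("`global_bad_channel_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(segment_channel_bad_uv = segment_channel_bad_uv,
         blink_uv = blink_uv, eye_move_uv = eye_move_uv,
         moving_avg_ms = moving_avg_ms,
         max_bad_channels_per_segment = max_bad_channels_per_segment,
         global_bad_channel_fraction = global_bad_channel_fraction,
         method = match.arg(method)),
    class = "artifact_criteria"
  )
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth band-pass
#' per channel, the standard digital realisation for ERP work since it
#' leaves component latencies untouched. Length and labels are unchanged.
#'
#' @param eeg An [eeg_continuous()].
#' @param low_hz,high_hz Band edges in Hz; defaults 0.3-30.
#' @param order Butterworth order per band edge (default 4; the effective
#'   roll-off after the forward-backward pass is twice that).
#' @return The filtered `eeg_continuous`, flagged as filtered.
#' @export
bandpass_filter <- function(eeg, low_hz = 0.3, high_hz = 30, order = 4) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  nyq <- eeg$sampling_rate_hz / 2
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq) {
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  for (i in seq_len(nrow(eeg$data))) {
    eeg$data[i, ] <- signal::filtfilt(bf, eeg$data[i, ])
  }
  eeg$filtered <- TRUE
  eeg
}

#' Moving-average max-minus-min of a trace
#'
#' The artifact statistic: smooth the trace with a centred boxcar of
#' `window_ms` (shrinking at the edges) and return its max minus min
#' (`method = "smooth_range"`), or return the largest max-minus-min seen
#' within any single boxcar-length window (`method = "windowed_range"`).
#'
#' @param trace Numeric single-channel trace (non-empty).
#' @param window_ms Boxcar length in ms (default 80).
#' @param rate_hz Sampling rate.
#' @param method See [artifact_criteria()].
#' @return Nonnegative range in the trace's units.
#' @export
moving_range <- function(trace, window_ms = 80, rate_hz = 1000,
                         method = c("smooth_range", "windowed_range")) {
  if (length(trace) == 0) stop("empty trace", call. = FALSE)
  method <- match.arg(method)
  hw <- floor(ms_to_samples(window_ms, rate_hz) / 2)
  n <- length(trace)
  if (method == "smooth_range") {
    sm <- boxcar_smooth(trace, hw)
    max(sm) - min(sm)
  } else {
    w <- min(2L * hw + 1L, n)
    shifts <- lapply(seq_len(w), function(k) trace[k:(n - w + k)])
    max(Reduce(pmax, shifts) - Reduce(pmin, shifts))
  }
}

# centred boxcar mean with shrinking edge windows, O(n) via cumsum
boxcar_smooth <- function(x, halfwidth) {
  n <- length(x)
  if (halfwidth < 1) return(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  hi <- pmin(i + halfwidth, n)
  lo <- pmax(i - halfwidth, 1L)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Segment continuous EEG into condition-locked epochs
#'
#' Cuts fixed windows around each target onset after adding the display
#' offset correction, keeping only the two analysis conditions:
#' human identity with a "natural" response (code 1) becomes
#' `human_natural`, AI identity with an "unnatural" response (code 2)
#' becomes `ai_unnatural`. All other events (discordant or missing
#' responses) are dropped and counted; events whose window falls outside
#' the record are dropped with a warning.
#'
#' @param eeg A band-pass filtered [eeg_continuous()].
#' @param events An [event_list()].
#' @param window_ms Epoch window in ms relative to the corrected onset,
#'   half-open (default `c(-200, 1000)`, i.e. 1200 samples at 1000 Hz).
#' @param offset_ms Display offset added to logged onsets (default 11 ms).
#' @param enforce_order Contract check that the input has been filtered
#'   (the pipeline order is filter, segment, detect, replace, baseline,
#'   re-reference); set `FALSE` only for controlled experiments.
#' @return An object of class `epoch_set`: `data` (epoch x channel x sample
#'   array), `condition`, `times_ms`, flags, and bookkeeping counts.
#' @export
segment_epochs <- function(eeg, events, window_ms = c(-200, 1000),
                           offset_ms = 11, enforce_order = TRUE) {
  stopifnot(inherits(eeg, "eeg_continuous"), inherits(events, "event_list"))
  if (enforce_order && !isTRUE(eeg$filtered)) {
    stop("pipeline order violation: segment_epochs() expects band-pass ",
         "filtered data (run bandpass_filter() first)", call. = FALSE)
  }
  rate <- eeg$sampling_rate_hz
  off <- ms_to_samples(offset_ms, rate)
  pre <- ms_to_samples(window_ms[1], rate)          # negative
  post <- ms_to_samples(window_ms[2], rate)
  n_samp <- post - pre                              # half-open window
  times_ms <- (pre + seq_len(n_samp) - 1L) * 1000 / rate

  cond <- ifelse(events$identity == "human" & events$response %in% 1L,
                 "human_natural",
          ifelse(events$identity == "AI" & events$response %in% 2L,
                 "ai_unnatural", NA_character_))
  n_discordant <- sum(is.na(cond))
  keep <- which(!is.na(cond))

  ns <- n_samples(eeg)
  start0 <- events$onset_sample[keep] + off + pre   # 0-based first sample
  in_bounds <- start0 >= 0L & (start0 + n_samp) <= ns
  if (any(!in_bounds)) {
    warning(sprintf("%d epoch(s) dropped: window outside the record",
                    sum(!in_bounds)), call. = FALSE)
  }
  keep <- keep[in_bounds]
  start0 <- start0[in_bounds]

  n_ep <- length(keep)
  n_ch <- nrow(eeg$data)
  data <- array(NA_real_, dim = c(n_ep, n_ch, n_samp),
                dimnames = list(NULL, eeg$channel_labels, NULL))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- eeg$data[, (start0[e] + 1L):(start0[e] + n_samp)]
  }

  structure(
    list(data = data,
         condition = cond[keep],
         times_ms = times_ms,
         sampling_rate_hz = rate,
         channel_labels = eeg$channel_labels,
         window_ms = window_ms,
         flags = rep("clean", n_ep),
         interpolated = matrix(FALSE, n_ep, n_ch,
                               dimnames = list(NULL, eeg$channel_labels)),
         baselined = FALSE, rereferenced = FALSE, replaced = FALSE,
         n_dropped_discordant = n_discordant,
         n_dropped_bounds = sum(!in_bounds)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs (%d clean) x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], sum(x$flags == "clean"), dim(x$data)[2], dim(x$data)[3],
    x$sampling_rate_hz))
  print(table(condition = x$condition))
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$data)[1]

#' Detect artifacts in segmented epochs
#'
#' Applies the moving-average max-minus-min rules: each scalp channel is bad
#' in a segment when its range exceeds the channel threshold; any channel
#' bad in more than the global fraction of segments is then marked bad in
#' all of them; finally a segment is rejected when it has more than the
#' allowed number of bad channels, a blink (vertical-ocular range above the
#' blink threshold) or an eye movement (horizontal-ocular range above the
#' eye-movement threshold). Ocular ranges are measured on the montage's
#' ocular channels (their mean when a role has several). Detection is a
#' pure function of the segmented data: rerunning it reproduces the same
#' report.
#'
#' @param epochs A segmented, not yet baseline-corrected [segment_epochs()]
#'   result.
#' @param criteria An [artifact_criteria()].
#' @param montage The recording montage (must declare ocular channels).
#' @return An object of class `artifact_report`: per-epoch/channel bad
#'   matrix, rejection flags and reasons, globally bad channels, counts.
#' @export
detect_artifacts <- function(epochs, criteria = artifact_criteria(),
                             montage) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(criteria, "artifact_criteria"),
            inherits(montage, "erp_montage"))
  if (n_epochs(epochs) == 0) stop("no epochs to screen", call. = FALSE)
  if (isTRUE(epochs$baselined) || isTRUE(epochs$rereferenced)) {
    stop("pipeline order violation: artifact detection runs on raw segments",
         call. = FALSE)
  }
  veog <- intersect(montage_channels(montage, "vertical-ocular"),
                    epochs$channel_labels)
  heog <- intersect(montage_channels(montage, "horizontal-ocular"),
                    epochs$channel_labels)
  if (length(veog) == 0 || length(heog) == 0) {
    stop("montage must provide vertical- and horizontal-ocular channels",
         call. = FALSE)
  }
  scalp <- intersect(montage_channels(montage, "scalp"),
                     epochs$channel_labels)
  rate <- epochs$sampling_rate_hz
  mr <- function(tr) moving_range(tr, criteria$moving_avg_ms, rate,
                                  criteria$method)
  n_ep <- n_epochs(epochs)

  ranges <- matrix(0, n_ep, length(scalp), dimnames = list(NULL, scalp))
  for (e in seq_len(n_ep)) {
    for (ci in seq_along(scalp)) {
      ranges[e, ci] <- mr(epochs$data[e, scalp[ci], ])
    }
  }
  channel_bad <- ranges > criteria$segment_channel_bad_uv

  global_bad <- scalp[colMeans(channel_bad) >
                        criteria$global_bad_channel_fraction]
  channel_bad[, global_bad] <- TRUE

  veog_range <- vapply(seq_len(n_ep), function(e) {
    mr(if (length(veog) == 1L) epochs$data[e, veog, ]
       else colMeans(epochs$data[e, veog, ]))
  }, numeric(1))
  heog_range <- vapply(seq_len(n_ep), function(e) {
    mr(if (length(heog) == 1L) epochs$data[e, heog, ]
       else colMeans(epochs$data[e, heog, ]))
  }, numeric(1))

  n_bad <- rowSums(channel_bad)
  too_many <- n_bad > criteria$max_bad_channels_per_segment
  blink <- veog_range > criteria$blink_uv
  eye <- heog_range > criteria$eye_move_uv

  reason <- rep(NA_character_, n_ep)
  reason[eye] <- "eye_movement"
  reason[blink] <- "blink"
  reason[too_many] <- "bad_channels"     # precedence: channels, blink, eye

  structure(
    list(channel_bad = channel_bad,
         epoch_rejected = too_many | blink | eye,
         reason = reason,
         rule = cbind(bad_channels = too_many, blink = blink,
                      eye_movement = eye),
         global_bad_channels = global_bad,
         scalp_channels = scalp,
         veog_range = veog_range, heog_range = heog_range,
         channel_ranges = ranges,
         counts = list(n_epochs = n_ep,
                       n_rejected = sum(too_many | blink | eye),
                       n_channel_flags = sum(channel_bad),
                       n_global_bad = length(global_bad))),
    class = "artifact_report"
  )
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf(
    "<artifact_report> %d/%d epochs rejected; %d globally bad channel(s)\n",
    x$counts$n_rejected, x$counts$n_epochs, x$counts$n_global_bad))
  if (x$counts$n_rejected > 0) print(table(reason = x$reason))
  invisible(x)
}

#' Write an artifact report to CSV
#' @param report An `artifact_report`.
#' @param path Output path.
#' @export
write_artifact_report_csv <- function(report, path) {
  df <- data.frame(epoch = seq_along(report$epoch_rejected),
                   rejected = report$epoch_rejected,
                   reason = report$reason,
                   n_bad_channels = rowSums(report$channel_bad),
                   veog_range_uv = report$veog_range,
                   heog_range_uv = report$heog_range)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Replace bad channels by neighbour interpolation
#'
#' Marks epochs rejected by the report, then replaces every bad channel's
#' trace in every retained epoch with the inverse-distance-weighted mean of
#' its good neighbours (montage geometry, chord distances). Good channels
#' are bit-unchanged. A bad channel with no good neighbour makes its epoch
#' unusable: it is rejected with reason `uninterpolatable`.
#'
#' @param epochs The [segment_epochs()] result the report was computed from.
#' @param report The matching [detect_artifacts()] report.
#' @param montage The recording montage.
#' @return The epoch set with rejection flags applied and bad channels
#'   interpolated (marked in `$interpolated`).
#' @export
replace_bad_channels <- function(epochs, report, montage) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(report, "artifact_report"),
            inherits(montage, "erp_montage"))
  if (nrow(report$channel_bad) != n_epochs(epochs)) {
    stop("report does not match the epoch set", call. = FALSE)
  }
  epochs$flags[report$epoch_rejected] <-
    paste0("rejected:", report$reason[report$epoch_rejected])

  scalp <- report$scalp_channels
  for (e in which(!report$epoch_rejected)) {
    bad <- scalp[report$channel_bad[e, ]]
    for (ch in bad) {
      nb <- intersect(montage$neighbor_map[[ch]], scalp)
      good_nb <- nb[!report$channel_bad[e, nb]]
      if (length(good_nb) == 0) {
        epochs$flags[e] <- "rejected:uninterpolatable"
        break
      }
      d <- sqrt(colSums((t(montage$positions[good_nb, , drop = FALSE]) -
                           montage$positions[ch, ])^2))
      w <- (1 / d) / sum(1 / d)
      nb_traces <- matrix(epochs$data[e, good_nb, ], nrow = length(good_nb))
      epochs$data[e, ch, ] <- colSums(nb_traces * w)
      epochs$interpolated[e, ch] <- TRUE
    }
  }
  epochs$replaced <- TRUE
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean voltage over the pre-stimulus
#' baseline interval, so the corrected baseline mean is zero.
#'
#' @param epochs An [segment_epochs()] result.
#' @param baseline_ms Baseline interval in ms, default `c(-200, 0)`
#'   (half-open).
#' @return The baseline-corrected epoch set.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (isTRUE(epochs$rereferenced)) {
    stop("pipeline order violation: baseline correction precedes ",
         "re-referencing", call. = FALSE)
  }
  sel <- epochs$times_ms >= baseline_ms[1] & epochs$times_ms < baseline_ms[2]
  if (!any(sel) || baseline_ms[1] < epochs$window_ms[1] ||
      baseline_ms[2] > epochs$window_ms[2]) {
    stop("baseline interval outside the epoch window", call. = FALSE)
  }
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over sample dim
  epochs$baselined <- TRUE
  epochs
}

#' Re-reference epochs to the average reference
#'
#' Subtracts, at every sample of every epoch, the instantaneous mean across
#' scalp channels, so the scalp channel sum is zero everywhere. Requires
#' baseline-corrected epochs whose bad channels have been replaced (or an
#' explicit `enforce_order = FALSE` for controlled experiments).
#'
#' @param epochs An [segment_epochs()] result.
#' @param montage Montage used to identify scalp channels; `NULL` treats
#'   every channel as scalp.
#' @param enforce_order Contract check on the pipeline order.
#' @return The re-referenced epoch set.
#' @export
rereference_average <- function(epochs, montage = NULL,
                                enforce_order = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (enforce_order && (!isTRUE(epochs$replaced) || !isTRUE(epochs$baselined))) {
    stop("pipeline order violation: re-referencing follows bad-channel ",
         "replacement and baseline correction", call. = FALSE)
  }
  scalp <- if (is.null(montage)) epochs$channel_labels else
    intersect(montage_channels(montage, "scalp"), epochs$channel_labels)
  si <- match(scalp, epochs$channel_labels)
  for (e in seq_len(n_epochs(epochs))) {
    m <- colMeans(epochs$data[e, si, , drop = FALSE][1, , , drop = TRUE])
    epochs$data[e, si, ] <- sweep(
      matrix(epochs$data[e, si, ], nrow = length(si)), 2, m, "-")
  }
  epochs$rereferenced <- TRUE
  epochs
}
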