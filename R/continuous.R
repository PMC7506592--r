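#' Continuous multichannel EEG
#'
#' Container for a raw recording: a channels x samples matrix of voltages in
#' microvolts, the sampling rate, ordered channel labels and the online
#' reference label (Cz for the vertex-referenced montage this pipeline
#' assumes).
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param reference Reference channel label (default `"Cz"`).
#' @return An object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, sampling_rate_hz, channel_labels,
                           reference = "Cz") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (nrow(data) != length(channel_labels)) {
    stop("row count of `data` must equal the number of channel labels",
         call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be > 0", call. = FALSE)
  }
  if (anyNA(data)) stop("`data` must not contain missing samples", call. = FALSE)
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate_hz = sampling_rate_hz,
         channel_labels = channel_labels, reference = reference,
         filtered = FALSE),
    class = "eeg_continuous"
  )
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz (ref %s%s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz, x$reference,
              if (isTRUE(x$filtered)) ", band-pass filtered" else ""))
  invisible(x)
}

n_samples <- function(eeg) ncol(eeg$data)

#' Event list for a prime-target paradigm
#'
#' One row per target presentation: 0-based onset sample, agent identity
#' (`human` or `AI`), the behavioural naturalness response (`1` = natural,
#' `2` = unnatural, `NA` = no response before the deadline) and reaction
#' time in ms.
#'
#' @param onset_sample Integer vector of 0-based onset samples, strictly
#'   increasing.
#' @param identity Character vector in `c("human", "AI")`.
#' @param response Integer vector with values 1, 2 or NA.
#' @param rt_ms Numeric reaction times in ms (NA when no response).
#' @return A `data.frame` of class `event_list`.
#' @export
event_list <- function(onset_sample, identity, response, rt_ms) {
  if (is.unsorted(onset_sample, strictly = TRUE)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  if (!all(identity %in% c("human", "AI"))) {
    stop("identity must be 'human' or 'AI'", call. = FALSE)
  }
  if (!all(response %in% c(1L, 2L) | is.na(response))) {
    stop("response codes must be 1 (natural), 2 (unnatural) or NA",
         call. = FALSE)
  }
  structure(
    data.frame(onset_sample = as.integer(onset_sample),
               identity = identity,
               response = as.integer(response),
               rt_ms = rt_ms),
    class = c("event_list", "data.frame")
  )
}

#' Write / read an event table
#'
#' Tab-separated file with columns `onset_sample`, `identity`, `response`,
#' `rt_ms`.
#'
#' @param events An `event_list`.
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  event_list(df$onset_sample, df$identity, df$response, df$rt_ms)
}
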