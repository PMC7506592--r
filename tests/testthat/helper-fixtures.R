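# Shared builders for small in-memory fixtures. Everything is generated in
# code; no data files.

# A flat (all-zero) recording with evenly spaced concordant events, already
# flagged as filtered so segmentation accepts it without running the filter.
flat_recording <- function(montage, n_events = 12, rate = 1000,
                           spacing_ms = 1600, lead_ms = 1000,
                           identity = rep(c("human", "AI"),
                                          length.out = n_events)) {
  total <- lead_ms + n_events * spacing_ms + 2000
  data <- matrix(0, nrow = length(montage$channel_labels),
                 ncol = round(total * rate / 1000))
  eeg <- eeg_continuous(data, rate, montage$channel_labels)
  eeg$filtered <- TRUE
  onsets <- round((lead_ms + (seq_len(n_events) - 1) * spacing_ms) *
                    rate / 1000)
  response <- ifelse(identity == "human", 1L, 2L)   # all concordant
  events <- event_list(onsets, identity, response,
                       rt_ms = rep(800, n_events))
  list(eeg = eeg, events = events)
}

# Segmented flat epochs ready for artifact construction
flat_epochs <- function(montage, n_events = 12, ...) {
  rec <- flat_recording(montage, n_events, ...)
  segment_epochs(rec$eeg, rec$events)
}

# Drive `channel` in epoch `e` beyond the 200 uV channel rule: a sustained
# square wave survives the 80 ms boxcar almost unchanged.
drive_channel <- function(epochs, e, channel, amplitude = 300) {
  n <- dim(epochs$data)[3]
  epochs$data[e, channel, seq(201, n - 200)] <- amplitude
  epochs
}

# Add a blink-shaped (300 ms half-sine) deflection on a channel of an epoch
add_half_sine <- function(epochs, e, channel, peak, at_sample = 400,
                          len = 300) {
  idx <- at_sample + seq_len(len)
  epochs$data[e, channel, idx] <- epochs$data[e, channel, idx] +
    peak * sin(pi * seq_len(len) / len)
  epochs
}

# A subject_average with Gaussian components of known peak amplitude at
# P7/P8 in both conditions (identical across conditions unless given).
bump_average <- function(montage, p1_peak = 5, n170_peak = -2,
                         rate = 1000, n_samp = 1200) {
  times <- seq_len(n_samp) - 1 - 200
  wave <- function(peak1, peak2) {
    w <- matrix(0, nrow = length(montage$channel_labels), ncol = n_samp,
                dimnames = list(montage$channel_labels, NULL))
    for (site in c("P7", "P8")) {
      w[site, ] <- peak1 * exp(-(times - 100)^2 / (2 * 12.5^2)) +
        peak2 * exp(-(times - 170)^2 / (2 * 12.5^2))
    }
    w
  }
  structure(
    list(waveforms = list(human_natural = wave(p1_peak, n170_peak),
                          ai_unnatural = wave(p1_peak, n170_peak)),
         n_epochs = c(human_natural = 10L, ai_unnatural = 10L),
         times_ms = times, sampling_rate_hz = rate,
         channel_labels = montage$channel_labels, complete = TRUE),
    class = "subject_average"
  )
}

# Independent exact two-sided Wilcoxon p by brute-force sign enumeration
# (test oracle; deliberately separate from the package implementation)
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(r)
  mu <- sum(r) / 2
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- drop(signs %*% r)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}
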