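#' Minimal EDF (European Data Format) I/O
#'
#' Writes and reads continuous EEG as EDF: ASCII header plus 16-bit
#' little-endian samples, physical units in microvolts. The writer stores
#' the whole recording as a single data record, which keeps the file exactly
#' sample-faithful (no trailing padding); amplitudes are quantised to the
#' 16-bit grid over a symmetric physical range, giving a resolution of
#' `range / 32767` microvolts.
#'
#' @param eeg An [eeg_continuous()].
#' @param path Output file path.
#' @param physical_max Symmetric physical range in microvolts; defaults to
#'   the smallest power-of-ten-ish bound covering the data, at least 1000.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns an
#'   [eeg_continuous()].
#' @export
write_edf <- function(eeg, path, physical_max = NULL) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  n_sig <- nrow(eeg$data)
  n_samp <- ncol(eeg$data)
  if (is.null(physical_max)) {
    physical_max <- max(1000, ceiling(max(abs(eeg$data)) * 1.01))
  }

  pad <- function(x, width) {
    x <- substr(as.character(x), 1L, width)
    formatC(x, width = width, flag = "-")
  }
  num8 <- function(x) pad(format(x, digits = 7, scientific = FALSE), 8L)

  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  record_dur <- n_samp / eeg$sampling_rate_hz
  header_bytes <- 256L + 256L * n_sig

  wchar(pad("0", 8))                               # version
  wchar(pad("X X X X", 80))                        # patient id (anonymous)
  wchar(pad(sprintf("Startdate X erpnat ref_%s", eeg$reference), 80))
  wchar(pad("01.01.00", 8))                        # start date
  wchar(pad("00.00.00", 8))                        # start time
  wchar(num8(header_bytes))
  wchar(pad("", 44))                               # reserved
  wchar(num8(1L))                                  # one data record
  wchar(num8(record_dur))
  wchar(pad(as.character(n_sig), 4))

  wchar(paste0(vapply(eeg$channel_labels, pad, "", width = 16L), collapse = ""))
  wchar(paste0(rep(pad("", 80), n_sig), collapse = ""))        # transducer
  wchar(paste0(rep(pad("uV", 8), n_sig), collapse = ""))       # dimension
  wchar(paste0(rep(num8(-physical_max), n_sig), collapse = ""))
  wchar(paste0(rep(num8(physical_max), n_sig), collapse = ""))
  wchar(paste0(rep(num8(-32767L), n_sig), collapse = ""))
  wchar(paste0(rep(num8(32767L), n_sig), collapse = ""))
  wchar(paste0(rep(pad("", 80), n_sig), collapse = ""))        # prefiltering
  wchar(paste0(rep(num8(n_samp), n_sig), collapse = ""))
  wchar(paste0(rep(pad("", 32), n_sig), collapse = ""))

  dig <- round(t(eeg$data) / physical_max * 32767)   # sample-major per signal
  dig <- pmin(pmax(dig, -32768), 32767)
  writeBin(as.integer(as.vector(dig)), con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(n) readChar(con, n, useBytes = TRUE)
  rtrim <- function(s) sub("\\s+$", "", s)

  rchar(8)                        # version
  rchar(80); recording <- rtrim(rchar(80))
  rchar(8); rchar(8); rchar(8); rchar(44)
  n_rec <- as.integer(rchar(8))
  rec_dur <- as.numeric(rchar(8))
  n_sig <- as.integer(rchar(4))

  labels <- rtrim(vapply(seq_len(n_sig), function(i) rchar(16), ""))
  rchar(80 * n_sig)               # transducer
  rchar(8 * n_sig)                # dimension
  pmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) rchar(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) rchar(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) rchar(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) rchar(8), ""))
  rchar(80 * n_sig)               # prefiltering
  spr <- as.integer(vapply(seq_len(n_sig), function(i) rchar(8), ""))
  rchar(32 * n_sig)

  total <- sum(spr) * n_rec
  dig <- readBin(con, what = "integer", n = total, size = 2L,
                 endian = "little", signed = TRUE)

  data <- matrix(0, nrow = n_sig, ncol = spr[1] * n_rec)
  idx <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      chunk <- dig[(idx + 1L):(idx + spr[s])]
      gain <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        pmin_[s] + (chunk - dmin_[s]) * gain
      idx <- idx + spr[s]
    }
  }

  reference <- if (grepl("ref_", recording)) {
    sub(".*ref_", "", recording)
  } else {
    "unknown"
  }
  eeg_continuous(data, sampling_rate_hz = spr[1] / rec_dur,
                 channel_labels = labels, reference = reference)
}
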