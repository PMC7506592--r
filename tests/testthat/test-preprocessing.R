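test_that("band-pass filter has the expected frequency response", {
  rate <- 1000
  t <- (0:9999) / rate
  mk <- function(x) {
    e <- eeg_continuous(matrix(x, nrow = 1), rate, "Cz")
    bandpass_filter(e)$data[1, ]
  }
  mid <- 3000:7000   # away from edge transients

  out50 <- mk(sin(2 * pi * 50 * t))
  expect_lt(max(abs(out50[mid])), 0.05)      # 50 Hz suppressed below 5%

  out10 <- mk(sin(2 * pi * 10 * t))
  expect_equal(max(abs(out10[mid])), 1, tolerance = 0.05)
  # zero phase: the filtered 10 Hz sine stays aligned with the input
  xc <- stats::ccf(out10[mid], sin(2 * pi * 10 * t)[mid], lag.max = 10,
                   plot = FALSE)
  expect_equal(xc$lag[which.max(xc$acf)], 0)

  # DC removal: the 0.3 Hz high-pass transient decays over seconds, so use
  # a 60 s record and check its middle third
  dc <- eeg_continuous(matrix(1, 1, 60000), rate, "Cz")
  outdc <- bandpass_filter(dc)$data[1, ]
  expect_lt(max(abs(outdc[20001:40000])), 1e-3)

  e <- eeg_continuous(matrix(0, 1, 100), rate, "Cz")
  expect_error(bandpass_filter(e, 0, 30), "Nyquist")
  expect_error(bandpass_filter(e, 0.3, 600), "Nyquist")
})

test_that("moving range implements boxcar-smoothed max minus min", {
  expect_equal(moving_range(rep(3.5, 500)), 0)

  # a single-sample 300 uV spike is diluted by the 81-sample boxcar
  tr <- rep(0, 1000); tr[500] <- 300
  expect_equal(moving_range(tr), 300 / 81, tolerance = 0.02)
  # ...but the windowed-range variant sees the full excursion
  expect_equal(moving_range(tr, method = "windowed_range"), 300)

  # a sustained 200 ms square step survives smoothing nearly intact
  tr2 <- rep(0, 1000); tr2[401:600] <- 150
  expect_equal(moving_range(tr2), 150, tolerance = 0.01)

  expect_error(moving_range(numeric(0)), "empty")
})

test_that("segmentation keeps only condition-concordant events", {
  m <- build_montage(16)
  n <- 60
  identity <- rep(c("human", "AI"), each = 30)
  response <- c(rep(1L, 25), rep(2L, 5),      # 25 human-natural
                rep(2L, 22), rep(1L, 8))      # 22 AI-unnatural
  rec <- flat_recording(m, n_events = n, identity = identity)
  events <- event_list(rec$events$onset_sample, identity, response,
                       rep(700, n))
  ep <- segment_epochs(rec$eeg, events)
  expect_equal(dim(ep$data)[1], 47)
  expect_equal(sum(ep$condition == "human_natural"), 25)
  expect_equal(sum(ep$condition == "ai_unnatural"), 22)
  expect_equal(ep$n_dropped_discordant, 13)
})

test_that("epoching aligns t = 0 to the offset-corrected onset", {
  m <- build_montage(16)
  rec <- flat_recording(m, n_events = 2)
  onset <- rec$events$onset_sample[1]
  # impulse 111 samples after the logged onset = 100 ms after the
  # offset-corrected onset (11 ms display offset at 1000 Hz)
  rec$eeg$data["P7", onset + 111 + 1] <- 42
  ep <- segment_epochs(rec$eeg, rec$events)
  expect_equal(unname(ep$data[1, "P7", which(ep$times_ms == 100)]), 42)
  expect_equal(sum(ep$data[1, "P7", ]), 42)   # single sample only
})

test_that("events whose window leaves the record are dropped with a warning", {
  m <- build_montage(16)
  rec <- flat_recording(m, n_events = 3)
  events <- event_list(c(50, rec$events$onset_sample[2:3]),
                       rec$events$identity, rec$events$response,
                       rec$events$rt_ms)
  expect_warning(ep <- segment_epochs(rec$eeg, events), "outside")
  expect_equal(dim(ep$data)[1], 2)
  expect_equal(ep$n_dropped_bounds, 1)
})

test_that("artifact detection applies the channel, blink and eye rules", {
  m <- build_montage(16)
  crit <- artifact_criteria()

  # clean epochs: nothing flagged
  ep <- flat_epochs(m, n_events = 10)
  r <- detect_artifacts(ep, crit, m)
  expect_equal(sum(r$epoch_rejected), 0)
  expect_equal(length(r$global_bad_channels), 0)
  expect_equal(sum(r$channel_bad), 0)

  # one channel hot in 30% of epochs becomes globally bad in all of them
  ep2 <- flat_epochs(m, n_events = 10)
  for (e in 1:3) ep2 <- drive_channel(ep2, e, "Oz", 300)
  r2 <- detect_artifacts(ep2, crit, m)
  expect_identical(r2$global_bad_channels, "Oz")
  expect_true(all(r2$channel_bad[, "Oz"]))
  expect_equal(sum(r2$epoch_rejected), 0)     # 1 bad channel <= 10 allowed

  # 11 hot channels reject the epoch for too many bad channels
  ep3 <- flat_epochs(m, n_events = 10)
  scalp <- montage_channels(m, "scalp")
  for (ch in scalp[1:11]) ep3 <- drive_channel(ep3, 4, ch, 300)
  r3 <- detect_artifacts(ep3, crit, m)
  expect_true(r3$epoch_rejected[4])
  expect_identical(r3$reason[4], "bad_channels")
  # ...while 10 hot channels do not
  ep4 <- flat_epochs(m, n_events = 10)
  for (ch in scalp[1:10]) ep4 <- drive_channel(ep4, 4, ch, 300)
  expect_false(detect_artifacts(ep4, crit, m)$epoch_rejected[4])

  # ocular rules, just above and just below threshold
  ep5 <- add_half_sine(flat_epochs(m, 10), 5, "VEOG", 160)
  expect_identical(detect_artifacts(ep5, crit, m)$reason[5], "blink")
  ep6 <- add_half_sine(flat_epochs(m, 10), 5, "VEOG", 120)
  expect_false(detect_artifacts(ep6, crit, m)$epoch_rejected[5])
})

test_that("artifact detection is idempotent, monotone and permutation-safe", {
  m <- build_montage(16)
  crit <- artifact_criteria()
  ep <- add_half_sine(flat_epochs(m, 8), 3, "VEOG", 200)
  ep <- drive_channel(ep, 6, "P4", 250)

  r1 <- detect_artifacts(ep, crit, m)
  expect_identical(r1, detect_artifacts(ep, crit, m))

  # scaling an artifact upward never rescues a rejected epoch
  ep_big <- add_half_sine(flat_epochs(m, 8), 3, "VEOG", 400)
  r_big <- detect_artifacts(ep_big, crit, m)
  expect_true(all(r_big$epoch_rejected[r1$epoch_rejected & seq_len(8) == 3]))
  expect_true(r_big$epoch_rejected[3])

  # permuting epochs permutes the report rows identically
  perm <- c(5, 1, 8, 3, 7, 2, 6, 4)
  ep_perm <- ep
  ep_perm$data <- ep$data[perm, , , drop = FALSE]
  ep_perm$condition <- ep$condition[perm]
  ep_perm$flags <- ep$flags[perm]
  ep_perm$interpolated <- ep$interpolated[perm, ]
  r_perm <- detect_artifacts(ep_perm, crit, m)
  expect_equal(r_perm$epoch_rejected, r1$epoch_rejected[perm])
  expect_equal(unname(r_perm$channel_bad), unname(r1$channel_bad[perm, ]))
})

test_that("detection requires ocular channels and raw segments", {
  m <- build_montage(16)
  ep <- flat_epochs(m, 4)
  no_ocular <- m
  no_ocular$roles[] <- "scalp"
  expect_error(detect_artifacts(ep, montage = no_ocular), "ocular")
  ep_b <- baseline_correct(ep)
  expect_error(detect_artifacts(ep_b, montage = m), "order")
})

test_that("bad channels are replaced by weighted neighbour means", {
  m <- build_montage(16)
  crit <- artifact_criteria()

  # give Oz's neighbours distinct traces; the interpolated trace must be
  # their inverse-distance weighted mean (computed independently here)
  ep <- flat_epochs(m, 10)
  ep <- drive_channel(ep, 2, "Oz", 300)
  nb <- m$neighbor_map[["Oz"]]
  d <- sqrt(colSums((t(m$positions[nb, ]) - m$positions["Oz", ])^2))
  w <- (1 / d) / sum(1 / d)
  for (i in seq_along(nb)) ep$data[2, nb[i], ] <- i * 10
  r <- detect_artifacts(ep, crit, m)
  fixed <- replace_bad_channels(ep, r, m)
  expect_equal(fixed$data[2, "Oz", ],
               rep(sum(w * (seq_along(nb) * 10)), dim(ep$data)[3]))
  expect_true(fixed$interpolated[2, "Oz"])
  # neighbours carrying an identical trace reproduce it exactly
  ep2 <- flat_epochs(m, 10)
  ep2 <- drive_channel(ep2, 3, "Oz", 300)
  for (ch in nb) ep2$data[3, ch, ] <- sin(seq_len(dim(ep2$data)[3]) / 50)
  fixed2 <- replace_bad_channels(ep2, detect_artifacts(ep2, crit, m), m)
  expect_equal(fixed2$data[3, "Oz", ], ep2$data[3, nb[1], ])

  # with no bad channels the data are bit-unchanged
  ep3 <- flat_epochs(m, 6)
  fixed3 <- replace_bad_channels(ep3, detect_artifacts(ep3, crit, m), m)
  expect_identical(fixed3$data, ep3$data)

  # a bad channel whose neighbours are all bad cannot be interpolated
  ep4 <- flat_epochs(m, 10)
  ep4 <- drive_channel(ep4, 2, "Oz", 300)
  for (ch in nb) ep4 <- drive_channel(ep4, 2, ch, 300)
  r4 <- detect_artifacts(ep4, crit, m)
  if (!r4$epoch_rejected[2]) {
    fixed4 <- replace_bad_channels(ep4, r4, m)
    expect_identical(fixed4$flags[2], "rejected:uninterpolatable")
  }
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  m <- build_montage(16)
  ep <- flat_epochs(m, 4)
  ep$data[1, "P3", ] <- 3.2
  ep$data[2, "P4", ] <- sin(seq_len(dim(ep$data)[3]) / 30) + 1.7
  bc <- baseline_correct(ep)
  base <- bc$times_ms >= -200 & bc$times_ms < 0
  expect_equal(mean(bc$data[1, "P3", base]), 0, tolerance = 1e-12)
  expect_equal(mean(bc$data[2, "P4", base]), 0, tolerance = 1e-12)
  expect_true(all(abs(bc$data[1, "P3", ]) < 1e-12))  # constant trace -> zero
  # an already zero-mean baseline leaves the trace unchanged
  expect_equal(bc$data[3, , ], ep$data[3, , ])
  expect_error(baseline_correct(ep, c(-500, 0)), "outside")
})

test_that("average re-referencing zeroes the scalp channel sum everywhere", {
  m <- build_montage(16)
  ep <- flat_epochs(m, 4)
  for (e in 1:4) ep$data[e, , ] <- matrix(rnorm(16 * dim(ep$data)[3]), 16)
  ep <- baseline_correct(ep)
  rr <- rereference_average(ep, m, enforce_order = FALSE)
  scalp <- montage_channels(m, "scalp")
  for (e in 1:4) {
    expect_lt(max(abs(colSums(rr$data[e, scalp, ]))), 1e-9)
  }
  # ocular channels are left on their original reference
  expect_equal(rr$data[1, "VEOG", ], ep$data[1, "VEOG", ])

  # a channel pair already at +1/-1 is its own average reference
  toy <- flat_epochs(m, 2)
  toy$data[1, , ] <- 0
  toy$data[1, "P7", ] <- 1
  toy$data[1, "P8", ] <- -1
  toy <- baseline_correct(toy)
  # (+1,-1) has zero mean only over those two channels; restrict montage-free
  two <- toy
  two$data <- toy$data[, c("P7", "P8"), , drop = FALSE]
  two$channel_labels <- c("P7", "P8")
  two$interpolated <- toy$interpolated[, c("P7", "P8")]
  rr2 <- rereference_average(two, montage = NULL, enforce_order = FALSE)
  expect_equal(rr2$data, two$data)

  # identical channels collapse to zero
  same <- flat_epochs(m, 2)
  same$data[1, , ] <- rep(sin(seq_len(dim(same$data)[3]) / 20),
                          each = 16)
  same <- baseline_correct(same)
  rr3 <- rereference_average(same, m, enforce_order = FALSE)
  expect_lt(max(abs(rr3$data[1, scalp, ])), 1e-12)
})

test_that("the pipeline order is enforced", {
  m <- build_montage(16)
  rec <- flat_recording(m, 4)
  raw <- rec$eeg
  raw$filtered <- FALSE
  expect_error(segment_epochs(raw, rec$events), "order")
  ep <- flat_epochs(m, 4)
  expect_error(rereference_average(ep, m), "order")   # before replace/baseline
  rr <- rereference_average(baseline_correct(ep), m, enforce_order = FALSE)
  expect_error(baseline_correct(rr), "order")         # baseline after reref
})

test_that("artifact-free data retain every concordant epoch end-to-end", {
  m <- build_montage(16)
  prof <- subject_profile(noise_sd = 3, blink_rate = 0, eye_move_rate = 0)
  rec <- simulate_recording(prof, paradigm_spec(n_trials_per_identity = 6),
                            m, seed = 13)
  concordant <- sum(rec$events$identity == "human" & rec$events$response == 1,
                    rec$events$identity == "AI" & rec$events$response == 2)
  pp <- preprocess_subject(rec$eeg, rec$events, m)
  expect_equal(sum(pp$epochs$flags == "clean"), concordant)
  expect_equal(sum(pp$epochs$condition == "human_natural" &
                     pp$epochs$flags == "clean") +
                 sum(pp$epochs$condition == "ai_unnatural" &
                       pp$epochs$flags == "clean"), concordant)
})
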