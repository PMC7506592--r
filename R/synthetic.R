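#' Paradigm timing specification
#'
#' Timing of the prime-target trial structure: three agent-image primes
#' (200 ms each), each followed by a 300 ms blank and a fixation cross
#' (200 ms after the first and second primes, 300 ms after the third), then
#' the target (agent image plus identity word) for 2000 ms and a 3000 ms
#' blank. Responses are accepted up to 5000 ms after target onset. Epoch
#' alignment downstream applies the +11 ms display-offset correction.
#'
#' @param n_trials_per_identity Trials per agent identity (default 30, i.e.
#'   a 60-trial main block).
#' @param prime_ms,prime_blank_ms,fixation_ms Prime phase durations in ms.
#' @param target_duration_ms,post_target_blank_ms,response_deadline_ms Target
#'   phase durations in ms.
#' @param onset_offset_ms Average stimulus display offset in ms, added to
#'   logged onsets at segmentation time.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param lead_in_ms,lead_out_ms Quiet padding before the first and after the
#'   last trial.
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_trials_per_identity = 30,
                          prime_ms = 200,
                          prime_blank_ms = 300,
                          fixation_ms = c(200, 200, 300),
                          target_duration_ms = 2000,
                          post_target_blank_ms = 3000,
                          response_deadline_ms = 5000,
                          onset_offset_ms = 11,
                          sampling_rate_hz = 1000,
                          lead_in_ms = 2000,
                          lead_out_ms = 2000) {
  durs <- c(prime_ms, prime_blank_ms, fixation_ms, target_duration_ms,
            post_target_blank_ms, lead_in_ms, lead_out_ms)
  if (any(durs <= 0)) stop("all durations must be > 0", call. = FALSE)
  if (response_deadline_ms < target_duration_ms) {
    stop("response deadline must be >= target duration", call. = FALSE)
  }
  pre_target_ms <- 3 * (prime_ms + prime_blank_ms) + sum(fixation_ms)
  structure(
    list(n_trials_per_identity = as.integer(n_trials_per_identity),
         prime_ms = prime_ms, prime_blank_ms = prime_blank_ms,
         fixation_ms = fixation_ms,
         target_duration_ms = target_duration_ms,
         post_target_blank_ms = post_target_blank_ms,
         response_deadline_ms = response_deadline_ms,
         onset_offset_ms = onset_offset_ms,
         sampling_rate_hz = sampling_rate_hz,
         lead_in_ms = lead_in_ms, lead_out_ms = lead_out_ms,
         pre_target_ms = pre_target_ms,
         trial_ms = pre_target_ms + target_duration_ms + post_target_blank_ms),
    class = "paradigm_spec"
  )
}

#' Ground-truth subject profile
#'
#' Everything the generator needs to know about one simulated participant.
#' Component amplitudes are given per 2 x 2 cell (identity human/AI by site
#' P7/P8) on the scale the analysis measures: the target adaptive-mean
#' amplitude in microvolts (the generator converts these to Gaussian peak
#' values internally, see [simulate_recording()]). Defaults reproduce the
#' study conditions: a face-over-text P1 modality effect (P8 > P7) with no
#' identity effect, and an identity-by-modality N170 interaction (human
#' face and AI text most negative).
#'
#' @param p1_amp_by_cell,n170_amp_by_cell 2 x 2 numeric matrices, rows
#'   `human`/`AI`, columns `P7`/`P8`, in adaptive-mean microvolts (N170
#'   values negative).
#' @param p1_latency_ms,n170_latency_ms Nominal peak latencies.
#' @param component_width_ms Gaussian bump width (4 standard deviations).
#' @param component_latency_jitter_sd Trial-to-trial latency jitter SD in ms.
#' @param noise_sd Additive white channel noise SD in microvolts.
#' @param blink_rate,eye_move_rate Ocular artifact rates in events/min.
#' @param bad_channel_ids Channels rendered unusable for the whole record.
#' @param p_natural_given_human,p_natural_given_AI Probability of a
#'   "natural" (code 1) response per identity.
#' @param rating_means Named list of per-instrument 7-point population means
#'   for `human` and `AI`.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(p1_amp_by_cell = default_cell_means("P1"),
                            n170_amp_by_cell = default_cell_means("N170"),
                            p1_latency_ms = 100,
                            n170_latency_ms = 170,
                            component_width_ms = 50,
                            component_latency_jitter_sd = 3,
                            noise_sd = 8,
                            blink_rate = 6,
                            eye_move_rate = 4,
                            bad_channel_ids = character(0),
                            p_natural_given_human = 0.85,
                            p_natural_given_AI = 0.15,
                            rating_means = default_rating_means()) {
  stopifnot_scalar_prob(p_natural_given_human, "p_natural_given_human")
  stopifnot_scalar_prob(p_natural_given_AI, "p_natural_given_AI")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  rm_ok <- vapply(rating_means, function(m) all(m >= 1 & m <= 7), logical(1))
  if (!all(rm_ok)) stop("rating means must lie in [1, 7]", call. = FALSE)
  cellify <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(c("human", "AI"), c("P7", "P8"))
    m
  }
  structure(
    list(p1_amp_by_cell = cellify(p1_amp_by_cell),
         n170_amp_by_cell = cellify(n170_amp_by_cell),
         p1_latency_ms = p1_latency_ms,
         n170_latency_ms = n170_latency_ms,
         component_width_ms = component_width_ms,
         component_latency_jitter_sd = component_latency_jitter_sd,
         noise_sd = noise_sd,
         blink_rate = blink_rate, eye_move_rate = eye_move_rate,
         bad_channel_ids = bad_channel_ids,
         p_natural_given_human = p_natural_given_human,
         p_natural_given_AI = p_natural_given_AI,
         rating_means = rating_means),
    class = "subject_profile"
  )
}

#' Population-level defaults for the simulated study
#'
#' `default_cell_means` returns the population 2 x 2 amplitude means
#' (microvolts, adaptive-mean scale): P1 carries a pure modality effect
#' (P8 5.76 vs P7 4.41 for both identities); N170 carries an
#' identity-by-modality interaction (human: P7 -0.83 / P8 -2.09; AI: P7
#' -2.27 / P8 -1.90). `default_rating_means` returns the 7-point instrument
#' means (attitude: human 3.05 / AI 3.83; naturalness: human 2.91 / AI
#' 3.57). `study_population` bundles these with the between-subject
#' variance components used by [cohort_profiles()] and
#' [simulate_amplitude_cohort()].
#'
#' @param component `"P1"` or `"N170"`.
#' @return See description.
#' @export
default_cell_means <- function(component = c("P1", "N170")) {
  component <- match.arg(component)
  m <- if (component == "P1") {
    rbind(human = c(P7 = 4.41, P8 = 5.76), AI = c(P7 = 4.41, P8 = 5.76))
  } else {
    rbind(human = c(P7 = -0.83, P8 = -2.09), AI = c(P7 = -2.27, P8 = -1.90))
  }
  m
}

#' @rdname default_cell_means
#' @export
default_rating_means <- function() {
  list(attitude = c(human = 3.05, AI = 3.83),
       naturalness = c(human = 2.91, AI = 3.57))
}

#' @rdname default_cell_means
#' @param offset_sd Between-subject SD of a common amplitude offset shared by
#'   the four cells of a component (microvolts).
#' @param cell_sd Between-subject SD of cell-specific deviations.
#' @param measurement_sd Residual per-cell measurement noise used by the
#'   direct amplitude simulator (approximates extraction noise after epoch
#'   averaging).
#' @export
study_population <- function(offset_sd = 2.5, cell_sd = 1.0,
                             measurement_sd = 0.8) {
  list(p1_means = default_cell_means("P1"),
       n170_means = default_cell_means("N170"),
       offset_sd = offset_sd, cell_sd = cell_sd,
       measurement_sd = measurement_sd)
}

# adaptive-mean gain of a unit-peak Gaussian bump on the sampling grid:
# mean of exp(-t^2 / (2 sd^2)) over samples within +/- halfwidth of the peak
adaptive_gain <- function(width_ms, halfwidth_ms, rate_hz) {
  sd_ms <- width_ms / 4
  hs <- ms_to_samples(halfwidth_ms, rate_hz)
  k <- (-hs):hs
  mean(exp(-(k * 1000 / rate_hz)^2 / (2 * sd_ms^2)))
}

#' Expected adaptive-mean amplitude of an injected Gaussian bump
#'
#' Closed-form (discrete-sum) value that [adaptive_mean()] returns for a
#' noise-free Gaussian component of a given peak amplitude; used to convert
#' between peak and adaptive-mean scales.
#'
#' @param peak_uv Peak amplitude in microvolts.
#' @param width_ms Bump width (4 SD) in ms.
#' @param halfwidth_ms Averaging halfwidth in ms.
#' @param rate_hz Sampling rate.
#' @return Expected adaptive-mean amplitude in microvolts.
#' @export
expected_adaptive_mean <- function(peak_uv, width_ms, halfwidth_ms = 10,
                                   rate_hz = 1000) {
  peak_uv * adaptive_gain(width_ms, halfwidth_ms, rate_hz)
}

#' Inject a Gaussian component into a single-channel trace
#'
#' Adds a smooth unimodal Gaussian bump (SD = `width_ms / 4`, support
#' truncated at 4 SD) peaking `latency_ms` after `onset_ms`, with peak value
#' equal to `amplitude`. The trace is assumed to start at time 0.
#'
#' @param signal Numeric single-channel trace.
#' @param onset_ms Stimulus onset time in ms.
#' @param latency_ms Component latency after onset in ms.
#' @param amplitude Peak amplitude in microvolts (negative for
#'   negative-going components).
#' @param width_ms Bump width (4 SD) in ms; must be > 0.
#' @param rate_hz Sampling rate in Hz.
#' @return The trace with the bump added.
#' @export
inject_component <- function(signal, onset_ms, latency_ms, amplitude,
                             width_ms, rate_hz = 1000) {
  if (width_ms <= 0) stop("`width_ms` must be > 0", call. = FALSE)
  sd_samp <- width_ms / 4 * rate_hz / 1000
  peak <- round((onset_ms + latency_ms) * rate_hz / 1000) + 1
  half_support <- ceiling(4 * sd_samp)
  lo <- peak - half_support
  hi <- peak + half_support
  if (peak < 1 || peak > length(signal) || hi > length(signal) || lo < 1) {
    stop("component bump extends outside the trace", call. = FALSE)
  }
  k <- lo:hi
  signal[k] <- signal[k] + amplitude * exp(-((k - peak)^2) / (2 * sd_samp^2))
  signal
}

#' Inject an ocular or bad-channel artifact
#'
#' `blink`: a 300 ms half-sine of peak `magnitude` on vertical-ocular
#' channels with a 40% copy on frontal scalp channels (y > 0.6).
#' `eye_move`: a 500 ms step of height `magnitude` (20 ms ramps) on
#' horizontal-ocular channels. `bad_channel`: a sustained 2 Hz oscillation
#' (peak-to-peak approximately `magnitude`) plus noise over the whole record
#' on one channel. Magnitudes are calibrated so the 80 ms moving-average
#' max-minus-min seen by the artifact detector approximately equals
#' `magnitude`.
#'
#' @param eeg An [eeg_continuous()].
#' @param kind `"blink"`, `"eye_move"` or `"bad_channel"`.
#' @param onset_ms Artifact onset in ms (ignored for `bad_channel`).
#' @param magnitude Microvolts, see above.
#' @param montage The recording's [build_montage()] montage.
#' @param channel For `bad_channel`: the channel label; defaults to the
#'   first scalp channel other than Cz, P7 and P8.
#' @return The modified `eeg_continuous`.
#' @export
inject_artifact <- function(eeg, kind, onset_ms, magnitude, montage,
                            channel = NULL) {
  stopifnot(inherits(eeg, "eeg_continuous"), inherits(montage, "erp_montage"))
  rate <- eeg$sampling_rate_hz
  ns <- n_samples(eeg)
  if (magnitude == 0) return(eeg)
  if (!kind %in% c("blink", "eye_move", "bad_channel")) {
    stop(sprintf("unknown artifact kind '%s'", kind), call. = FALSE)
  }

  add_to <- function(eeg, labels, template, start) {
    idx <- start + seq_along(template) - 1L
    keep <- idx >= 1L & idx <= ns
    for (lab in labels) {
      if (lab %in% eeg$channel_labels) {
        eeg$data[lab, idx[keep]] <- eeg$data[lab, idx[keep]] + template[keep]
      }
    }
    eeg
  }

  if (kind == "blink") {
    if (onset_ms < 0 || onset_ms / 1000 > ns / rate) {
      stop("blink onset outside the record", call. = FALSE)
    }
    len <- ms_to_samples(300, rate)
    template <- magnitude * sin(pi * seq_len(len) / len)
    start <- ms_to_samples(onset_ms, rate) + 1L
    veog <- montage_channels(montage, "vertical-ocular")
    frontal <- montage_channels(montage, "scalp")
    frontal <- frontal[montage$positions[frontal, 2] > 0.6]
    eeg <- add_to(eeg, veog, template, start)
    eeg <- add_to(eeg, frontal, 0.4 * template, start)
  } else if (kind == "eye_move") {
    if (onset_ms < 0 || onset_ms / 1000 > ns / rate) {
      stop("eye movement onset outside the record", call. = FALSE)
    }
    ramp <- ms_to_samples(20, rate)
    plateau <- ms_to_samples(460, rate)
    template <- magnitude * c(seq_len(ramp) / ramp, rep(1, plateau),
                              rev(seq_len(ramp)) / ramp)
    start <- ms_to_samples(onset_ms, rate) + 1L
    heog <- montage_channels(montage, "horizontal-ocular")
    eeg <- add_to(eeg, heog, template, start)
  } else {
    if (is.null(channel)) {
      scalp <- montage_channels(montage, "scalp")
      channel <- setdiff(scalp, c("Cz", "P7", "P8"))[1]
    }
    t <- seq_len(ns) / rate
    eeg$data[channel, ] <- eeg$data[channel, ] +
      magnitude / 2 * sin(2 * pi * 2 * t) +
      stats::rnorm(ns, sd = magnitude / 10)
  }
  eeg
}

#' Simulate one subject's continuous recording and event table
#'
#' Builds a Cz-referenced continuous record for the full 60-trial
#' prime-target block: white channel noise, P1 and N170 Gaussian components
#' at P7 and P8 with cell-dependent amplitudes and shared trial-wise latency
#' jitter, Poisson-scheduled blinks and horizontal eye movements, and any
#' profile-declared globally bad channels. Behavioural responses are drawn
#' per identity from the profile's naturalness probabilities; reaction times
#' are log-normal truncated at the response deadline. Cell amplitudes are
#' interpreted on the adaptive-mean scale (halfwidth `halfwidth_ms`), so a
#' noise-free record yields downstream adaptive means equal to the profile
#' values.
#'
#' @param profile A [subject_profile()].
#' @param paradigm A [paradigm_spec()].
#' @param montage A [build_montage()] montage.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param halfwidth_ms Adaptive-mean halfwidth assumed for the amplitude
#'   scale (default 10 ms, matching [component_window()]).
#' @return List with elements `eeg` ([eeg_continuous()]) and `events`
#'   ([event_list()]).
#' @export
simulate_recording <- function(profile, paradigm, montage, seed,
                               halfwidth_ms = 10) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(paradigm, "paradigm_spec"))
  validate_montage(montage)
  rate <- paradigm$sampling_rate_hz

  with_seed(seed, {
    npi <- paradigm$n_trials_per_identity
    n_trials <- 2L * npi
    identity <- sample(rep(c("human", "AI"), each = npi))
    total_ms <- paradigm$lead_in_ms + n_trials * paradigm$trial_ms +
      paradigm$lead_out_ms
    ns <- ms_to_samples(total_ms, rate)
    labels <- montage$channel_labels

    data <- matrix(stats::rnorm(length(labels) * ns, sd = profile$noise_sd),
                   nrow = length(labels), dimnames = list(labels, NULL))

    onset_ms <- paradigm$lead_in_ms +
      (seq_len(n_trials) - 1) * paradigm$trial_ms + paradigm$pre_target_ms
    onset_sample <- ms_to_samples(onset_ms, rate)   # 0-based

    p_nat <- ifelse(identity == "human",
                    profile$p_natural_given_human,
                    profile$p_natural_given_AI)
    response <- ifelse(stats::runif(n_trials) < p_nat, 1L, 2L)
    rt_ms <- stats::rlnorm(n_trials, meanlog = log(900), sdlog = 0.35)
    while (any(rt_ms >= paradigm$response_deadline_ms)) {
      bad <- rt_ms >= paradigm$response_deadline_ms
      rt_ms[bad] <- stats::rlnorm(sum(bad), meanlog = log(900), sdlog = 0.35)
    }

    gain <- adaptive_gain(profile$component_width_ms, halfwidth_ms, rate)
    sd_samp <- profile$component_width_ms / 4 * rate / 1000
    hs <- ceiling(4 * sd_samp)
    tmpl <- exp(-((-hs):hs)^2 / (2 * sd_samp^2))
    comps <- list(
      list(amp = profile$p1_amp_by_cell, lat = profile$p1_latency_ms),
      list(amp = profile$n170_amp_by_cell, lat = profile$n170_latency_ms)
    )
    # the analysis epoch aligns t=0 to onset + the 11 ms display offset, so
    # physiological latencies are placed relative to the corrected onset
    eff_onset_ms <- onset_ms + paradigm$onset_offset_ms
    site_rows <- match(c("P7", "P8"), labels)
    for (tr in seq_len(n_trials)) {
      for (cmp in comps) {
        jitter <- stats::rnorm(1, 0, profile$component_latency_jitter_sd)
        pk <- round((eff_onset_ms[tr] + cmp$lat + jitter) * rate / 1000) + 1
        idx <- (pk - hs):(pk + hs)
        for (si in 1:2) {
          peak <- cmp$amp[identity[tr], c("P7", "P8")[si]] / gain
          data[site_rows[si], idx] <- data[site_rows[si], idx] + peak * tmpl
        }
      }
    }
    eeg <- eeg_continuous(data, rate, labels, reference = "Cz")

    dur_min <- total_ms / 60000
    schedule <- function(rate_per_min) {
      n <- stats::rpois(1, rate_per_min * dur_min)
      sort(stats::runif(n, 500, total_ms - 1000))
    }
    for (t0 in schedule(profile$blink_rate)) {
      mag <- min(max(stats::rnorm(1, 200, 25), 160), 300)
      eeg <- inject_artifact(eeg, "blink", t0, mag, montage)
    }
    for (t0 in schedule(profile$eye_move_rate)) {
      mag <- min(max(stats::rnorm(1, 80, 10), 60), 120)
      eeg <- inject_artifact(eeg, "eye_move", t0, mag, montage)
    }
    for (ch in profile$bad_channel_ids) {
      eeg <- inject_artifact(eeg, "bad_channel", 0, 300, montage, channel = ch)
    }

    list(eeg = eeg,
         events = event_list(onset_sample, identity, response, rt_ms))
  })
}

#' Simulate 7-point rating tables
#'
#' Draws per-subject, per-agent item responses for the attitude (three
#' semantic-differential items) and perceived-naturalness (three items)
#' instruments. A subject trait shared across agents, an agent-specific
#' deviation, and per-item noise are added to the profile's population
#' means; items are rounded to the 1-7 integer scale and each instrument's
#' score is the exact arithmetic mean of its three items.
#'
#' @param profile A [subject_profile()] (only `rating_means` is used).
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param trait_sd,agent_sd,item_sd Noise SDs for the three levels (set all
#'   to 0 for deterministic means).
#' @return A data.frame with columns `subject`, `agent`, `instrument`,
#'   `item1`-`item3`, `mean_score`.
#' @export
simulate_ratings <- function(profile, n_subjects, seed,
                             trait_sd = 0.5, agent_sd = 0.5, item_sd = 0.8) {
  stopifnot(inherits(profile, "subject_profile"))
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      trait <- stats::rnorm(1, 0, trait_sd)
      for (inst in names(profile$rating_means)) {
        for (agent in c("human", "AI")) {
          latent <- profile$rating_means[[inst]][[agent]] + trait +
            stats::rnorm(1, 0, agent_sd)
          items <- round(latent + stats::rnorm(3, 0, item_sd))
          items <- pmin(pmax(items, 1L), 7L)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, agent = agent, instrument = inst,
            item1 = items[1], item2 = items[2], item3 = items[3],
            mean_score = mean(items))
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Draw a cohort of subject profiles
#'
#' Adds between-subject variability around the population cell means: a
#' common offset per component (shared by its four cells) and independent
#' cell-specific deviations.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param population A [study_population()] list.
#' @param ... Additional arguments passed to every [subject_profile()] call
#'   (e.g. `noise_sd`, `bad_channel_ids`).
#' @return List of `subject_profile` objects.
#' @export
cohort_profiles <- function(n_subjects, seed, population = study_population(),
                            ...) {
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      dev <- function(means) {
        means + stats::rnorm(1, 0, population$offset_sd) +
          matrix(stats::rnorm(4, 0, population$cell_sd), 2, 2)
      }
      subject_profile(p1_amp_by_cell = dev(population$p1_means),
                      n170_amp_by_cell = dev(population$n170_means), ...)
    })
  })
}

#' Simulate an amplitude table directly from the cohort model
#'
#' Bypasses the EEG layer: draws per-subject cell amplitudes (common offset
#' + cell deviation + measurement residual) around the population means.
#' Useful for Monte-Carlo power and type-I-error studies of the statistical
#' layer at negligible cost.
#'
#' @inheritParams cohort_profiles
#' @return A long-format amplitude table: `subject`, `component`,
#'   `identity`, `site`, `amplitude_uv` (class `amplitude_table`).
#' @export
simulate_amplitude_cohort <- function(n_subjects, seed,
                                      population = study_population()) {
  with_seed(seed, {
    means <- list(P1 = population$p1_means, N170 = population$n170_means)
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (cmp in names(means)) {
        cells <- means[[cmp]] + stats::rnorm(1, 0, population$offset_sd) +
          matrix(stats::rnorm(4, 0, population$cell_sd), 2, 2) +
          matrix(stats::rnorm(4, 0, population$measurement_sd), 2, 2)
        for (id in c("human", "AI")) {
          for (site in c("P7", "P8")) {
            rows[[length(rows) + 1L]] <- data.frame(
              subject = s, component = cmp, identity = id, site = site,
              amplitude_uv = cells[id, site])
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("amplitude_table", "data.frame")
    out
  })
}
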