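#' Synthetic subject profile
#'
#' Parameters of one simulated sleeper. The generated recording contains a
#' quasi-periodic respiratory wrist motion (frequency jittered around
#' `resp_freq`), cardiac micro-vibrations (a heartbeat impulse train
#' convolved with a damped oscillation at `cardiac_freq`), sporadic gross
#' body-movement bursts (band-limited 2-3 Hz noise), white sensor noise,
#' and quantisation at the sensor resolutions (0.0153 mG, 0.0000153 dps).
#' Apnea/hypopnea events are placed by a renewal process with a 10 s
#' refractory gap; each event suppresses the respiratory amplitude with a
#' deepening profile (depth grows from ~60% of its peak to a peak drawn per
#' event type, apneas reaching 0.8-0.95, hypopneas 0.6-0.8) and ends with a
#' 2-3x recovery breath. Central apneas additionally destabilise the
#' cardiac resonance; obstructive and mixed events keep a small residual
#' paradoxical motion.
#'
#' @param subject_id Identifier.
#' @param target_ahi Target events per hour (the realised count is Poisson).
#' @param hours Recording duration in hours.
#' @param sample_rate Sampling rate in Hz (60).
#' @param resp_freq Mean breathing frequency in Hz (0.25); must lie in the
#'   respiratory band (0.13, 0.70).
#' @param resp_freq_jitter SD of the slow breathing-frequency wander (Hz).
#' @param breath_amp_sd Log-SD of per-breath amplitude variability.
#' @param heart_rate Beats per minute.
#' @param cardiac_freq Cardiac resonance frequency in Hz, inside (4, 11).
#' @param movement_rate Gross movement bursts per hour.
#' @param event_duration Event duration range in seconds (10-60).
#' @param event_type_mix Named proportions over the four event types; the
#'   default keeps the 79/17/4 obstructive/central/mixed split among apneas
#'   with hypopneas at 55% of all events.
#' @param amplitudes Named list of channel scales: respiratory, cardiac and
#'   movement amplitudes plus white-noise SDs, for each sensor (G and dps).
#' @param seed Integer seed: the same profile always generates a
#'   bit-identical recording.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(subject_id = "synthetic",
                            target_ahi = 15,
                            hours = 8,
                            sample_rate = 60,
                            resp_freq = 0.25,
                            resp_freq_jitter = 0.015,
                            breath_amp_sd = 0.1,
                            heart_rate = 60,
                            cardiac_freq = 7.5,
                            movement_rate = 5,
                            event_duration = c(10, 60),
                            event_type_mix = c(obstructive_apnea = 0.45 * 0.79,
                                               central_apnea = 0.45 * 0.17,
                                               mixed_apnea = 0.45 * 0.04,
                                               hypopnea = 0.55),
                            amplitudes = list(resp_acc = 4e-3, resp_gyr = 0.4,
                                              cardiac_acc = 1.5e-3, cardiac_gyr = 0.15,
                                              movement_acc = 0.05, movement_gyr = 5,
                                              noise_acc = 3e-4, noise_gyr = 0.03),
                            seed = 1) {
  stopifnot(target_ahi >= 0, hours > 0,
            resp_freq > 0.13, resp_freq < 0.70,
            cardiac_freq > 4, cardiac_freq < 11,
            length(event_duration) == 2, event_duration[1] > 0)
  if (abs(sum(event_type_mix) - 1) > 1e-8) {
    abort("`event_type_mix` must sum to 1.", class = "somnimu_format_error")
  }
  if (!setequal(names(event_type_mix), annotation_types())) {
    abort("`event_type_mix` must name the four annotation types.",
          class = "somnimu_format_error")
  }
  structure(list(subject_id = subject_id, target_ahi = target_ahi,
                 hours = hours, sample_rate = sample_rate,
                 resp_freq = resp_freq, resp_freq_jitter = resp_freq_jitter,
                 breath_amp_sd = breath_amp_sd,
                 heart_rate = heart_rate, cardiac_freq = cardiac_freq,
                 movement_rate = movement_rate,
                 event_duration = event_duration,
                 event_type_mix = event_type_mix,
                 amplitudes = amplitudes, seed = seed),
            class = "subject_profile")
}

acc_resolution <- 0.0153e-3    # G (0.0153 mG)
gyr_resolution <- 0.0000153    # dps

# slow AR(1) wander interpolated to the sample grid
slow_wander <- function(n, fs, sd, tau = 30) {
  n_coarse <- ceiling(n / fs) + 2
  a <- exp(-1 / tau)
  innov <- rnorm(n_coarse, 0, sd * sqrt(1 - a^2))
  z <- as.numeric(stats::filter(innov, a, method = "recursive"))
  approx(seq(0, by = 1, length.out = n_coarse), z,
         xout = (seq_len(n) - 1) / fs, rule = 2)$y
}

place_events <- function(n_events, durations, total, refractory = 10) {
  busy <- sum(durations) + n_events * refractory
  gaps <- rexp(n_events + 1)
  gaps <- gaps / sum(gaps) * (total - busy)
  onset <- numeric(n_events)
  tcur <- 0
  for (i in seq_len(n_events)) {
    tcur <- tcur + gaps[i]
    onset[i] <- tcur
    tcur <- tcur + durations[i] + refractory
  }
  onset
}

#' Generate one synthetic subject
#'
#' Builds the 60 Hz six-axis recording described in [subject_profile()]
#' together with its ground truth (event annotations, true AHI and movement
#' times). The generator writes the same CSV dialects the readers parse, so
#' the pipeline can be exercised end-to-end through its public interfaces.
#'
#' @param profile A [subject_profile()].
#' @return List with `recording` (an [imu_recording()]) and `truth` (list of
#'   `events`, `true_ahi`, `movement_times`).
#' @export
generate_subject <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  withr::with_seed(profile$seed, generate_subject_impl(profile))
}

generate_subject_impl <- function(p) {
  fs <- p$sample_rate
  total <- p$hours * 3600
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- p$amplitudes

  ## --- events -------------------------------------------------------------
  # the requested configuration must fit: expected occupancy (mean duration
  # plus the 10 s refractory gap per event) within 90% of the recording
  mean_occupancy <- p$target_ahi * p$hours *
    (mean(p$event_duration) + 10)
  if (mean_occupancy > 0.9 * total) {
    abort("Requested events do not fit the recording duration.",
          class = "somnimu_data_error")
  }
  n_ev <- rpois(1, p$target_ahi * p$hours)
  if (n_ev > 0) {
    durations <- runif(n_ev, p$event_duration[1], p$event_duration[2])
    # cap an upward Poisson fluctuation at what physically fits
    while (n_ev > 0 && sum(durations) + n_ev * 10 > 0.9 * total) {
      n_ev <- n_ev - 1L
      durations <- durations[seq_len(n_ev)]
    }
  }
  if (n_ev > 0) {
    onsets <- place_events(n_ev, durations, total)
    types <- sample(names(p$event_type_mix), n_ev, replace = TRUE,
                    prob = p$event_type_mix)
    events <- tibble::tibble(event_type = types, onset = onsets,
                             duration = durations)
  } else {
    events <- tibble::tibble(event_type = character(), onset = numeric(),
                             duration = numeric())
  }

  ## --- respiratory gating by events ---------------------------------------
  # deepening suppression: depth ramps from 60% of its peak to the peak,
  # then a recovery breath (2-3x) decaying over ~4 s
  gate <- rep(1, n)
  central_mask <- rep(FALSE, n)
  paradox <- rep(0, n)
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, floor(events$onset[i] * fs) + 1L)
    i1 <- min(n, ceiling((events$onset[i] + events$duration[i]) * fs))
    if (i0 >= i1) next
    is_apnea <- events$event_type[i] != "hypopnea"
    d_peak <- if (is_apnea) runif(1, 0.80, 0.95) else runif(1, 0.60, 0.80)
    frac <- (seq(i0, i1) - i0) / (i1 - i0)
    depth <- d_peak * (0.6 + 0.4 * frac)
    gate[i0:i1] <- pmin(gate[i0:i1], 1 - depth)
    if (events$event_type[i] == "central_apnea") {
      central_mask[i0:i1] <- TRUE
    } else if (is_apnea) {
      # residual paradoxical motion during obstructed effort
      paradox[i0:i1] <- 0.1 * d_peak
    }
    r0 <- i1 + 1L
    r1 <- min(n, i1 + round(4 * fs))
    if (r0 <= r1) {
      boost <- runif(1, 2, 3)
      gate[r0:r1] <- pmax(gate[r0:r1],
                          1 + (boost - 1) * exp(-(seq(r0, r1) - r0) / (1.5 * fs)))
    }
  }

  ## --- respiration ---------------------------------------------------------
  freq <- p$resp_freq + slow_wander(n, fs, p$resp_freq_jitter)
  freq <- pmin(pmax(freq, 0.14), 0.69)
  phase <- 2 * pi * cumsum(freq) / fs
  n_breaths <- ceiling(total * p$resp_freq) + 2
  bamp <- rlnorm(n_breaths, 0, p$breath_amp_sd)
  breath_amp <- approx(seq(0, by = 1 / p$resp_freq, length.out = n_breaths),
                       bamp, xout = t, method = "constant", rule = 2)$y
  resp_base <- breath_amp * (gate * sin(phase) + paradox * sin(phase + pi))

  unit_vec <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  resp_dir_acc <- unit_vec()
  resp_dir_gyr <- unit_vec()
  resp_lag <- runif(3, 0, 0.4)  # small per-axis phase offsets (rad)

  ## --- cardiac -------------------------------------------------------------
  beat_dt <- 60 / p$heart_rate
  n_beats <- ceiling(total / beat_dt) + 2
  ivl <- beat_dt * exp(rnorm(n_beats, 0, 0.03))
  beat_times <- cumsum(ivl)
  beat_times <- beat_times[beat_times < total - 0.5]
  beat_idx <- floor(beat_times * fs) + 1L
  in_central <- central_mask[beat_idx]
  beat_freq <- p$cardiac_freq + rnorm(length(beat_times),
                                      0, ifelse(in_central, 1.5, 0.15))
  beat_freq <- pmin(pmax(beat_freq, 4.2), 10.8)
  klen <- round(0.4 * fs)
  tau <- seq(0, klen - 1) / fs
  cardiac <- numeric(n + klen)
  for (b in seq_along(beat_times)) {
    kern <- exp(-tau / 0.08) * sin(2 * pi * beat_freq[b] * tau)
    ii <- beat_idx[b]:(beat_idx[b] + klen - 1L)
    cardiac[ii] <- cardiac[ii] + kern
  }
  cardiac <- cardiac[seq_len(n)]
  card_dir_acc <- unit_vec()
  card_dir_gyr <- unit_vec()

  ## --- gross movements ------------------------------------------------------
  n_mov <- rpois(1, p$movement_rate * p$hours)
  movement_times <- sort(runif(n_mov, 0, total - 8))
  mov_acc <- matrix(0, n, 3)
  mov_gyr <- matrix(0, n, 3)
  if (n_mov > 0) {
    bm_taps <- 199
    for (m in seq_len(n_mov)) {
      dur <- runif(1, 2, 6)
      len <- round(dur * fs)
      i0 <- floor(movement_times[m] * fs) + 1L
      i1 <- min(n, i0 + len - 1L)
      len <- i1 - i0 + 1L
      if (len < 4) next
      padded <- bandpass_fir(rnorm(len + 2L * bm_taps), 2.0, 3.0, fs,
                             taps = bm_taps)
      burst <- padded[(bm_taps + 1L):(bm_taps + len)]
      taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
      burst <- burst * taper / max(abs(burst), 1e-12)
      wa <- abs(rnorm(3, 1, 0.3))
      wg <- abs(rnorm(3, 1, 0.3))
      for (ax in 1:3) {
        mov_acc[i0:i1, ax] <- mov_acc[i0:i1, ax] + amp$movement_acc * wa[ax] * burst
        mov_gyr[i0:i1, ax] <- mov_gyr[i0:i1, ax] + amp$movement_gyr * wg[ax] * burst
      }
    }
  }

  ## --- assemble, add noise, quantise ---------------------------------------
  axes <- list()
  for (ax in 1:3) {
    resp_ax <- breath_amp * (gate * sin(phase + resp_lag[ax]) +
                               paradox * sin(phase + pi + resp_lag[ax]))
    axes[[ax]] <- amp$resp_acc * resp_dir_acc[ax] * resp_ax +
      amp$cardiac_acc * card_dir_acc[ax] * cardiac +
      mov_acc[, ax] + rnorm(n, 0, amp$noise_acc)
    axes[[ax + 3]] <- amp$resp_gyr * resp_dir_gyr[ax] * resp_ax +
      amp$cardiac_gyr * card_dir_gyr[ax] * cardiac +
      mov_gyr[, ax] + rnorm(n, 0, amp$noise_gyr)
  }
  dat <- tibble::tibble(
    ax = round(axes[[1]] / acc_resolution) * acc_resolution,
    ay = round(axes[[2]] / acc_resolution) * acc_resolution,
    az = round(axes[[3]] / acc_resolution) * acc_resolution,
    gx = round(axes[[4]] / gyr_resolution) * gyr_resolution,
    gy = round(axes[[5]] / gyr_resolution) * gyr_resolution,
    gz = round(axes[[6]] / gyr_resolution) * gyr_resolution
  )
  list(
    recording = imu_recording(dat, subject_id = p$subject_id,
                              sample_rate = fs),
    truth = list(events = events,
                 true_ahi = nrow(events) / p$hours,
                 movement_times = movement_times)
  )
}

#' Profiles for a synthetic cohort
#'
#' Allocates subjects across the four severity classes
#' (normal/mild/moderate/severe at 20/30/25/25%) and draws each subject's
#' target AHI uniformly within its class band (clipped to `ahi_range`),
#' giving a right-skewed cohort whose median sits in the mild range with
#' all severities represented. Heart rate, cardiac resonance and movement
#' rate vary across subjects; per-subject seeds derive reproducibly from
#' `seed`.
#'
#' @param n Number of subjects.
#' @param ahi_range Span of target AHI values (events/hour).
#' @param hours Recording duration per subject.
#' @param seed Integer seed.
#' @return List of [subject_profile()] objects.
#' @export
cohort_profiles <- function(n = 20, ahi_range = c(0, 60), hours = 2, seed = 1) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    props <- c(normal = 0.20, mild = 0.30, moderate = 0.25, severe = 0.25)
    counts <- floor(props * n)
    rem <- props * n - counts
    short <- n - sum(counts)
    if (short > 0) {
      ord <- order(rem, decreasing = TRUE)
      counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
    }
    lo <- c(normal = 0.5, mild = 5, moderate = 15, severe = 30)
    hi <- c(normal = 5, mild = 15, moderate = 30, severe = 60)
    classes <- rep(names(props), counts)
    ahi <- runif(n, pmax(lo[classes], ahi_range[1]),
                 pmin(hi[classes], ahi_range[2]))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      subject_profile(subject_id = sprintf("S%03d", i),
                      target_ahi = ahi[i],
                      hours = hours,
                      heart_rate = runif(1, 52, 78),
                      cardiac_freq = runif(1, 5, 10),
                      movement_rate = runif(1, 2, 8),
                      seed = seeds[i])
    })
  })
}

#' Generate a synthetic cohort
#'
#' @inheritParams cohort_profiles
#' @return List with one element per subject, each as returned by
#'   [generate_subject()], with the profile attached as `$profile`.
#' @export
generate_cohort <- function(n = 20, ahi_range = c(0, 60), hours = 2, seed = 1) {
  profiles <- cohort_profiles(n, ahi_range, hours, seed)
  lapply(profiles, function(p) {
    out <- generate_subject(p)
    out$profile <- p
    out
  })
}

#' Feature tables for a whole cohort, one subject at a time
#'
#' Generates each profile's recording, extracts its epoch feature table and
#' discards the raw signals before moving on, so whole cohorts fit in
#' memory. Ground-truth labels come from the generated annotations.
#'
#' @param profiles List of [subject_profile()]s (e.g. [cohort_profiles()]).
#' @param label_rule Passed to [label_epochs()].
#' @param verbose Print one line per subject.
#' @return List with `epochs` (pooled labelled feature table) and
#'   `subjects` (tibble of `subject_id`, `ahi` = true AHI, `n_epochs`).
#' @export
cohort_feature_table <- function(profiles, label_rule = "end", verbose = FALSE) {
  per_subject <- lapply(profiles, function(p) {
    gen <- generate_subject(p)
    tbl <- build_feature_table(gen$recording, gen$truth$events,
                               label_rule = label_rule)
    if (verbose) {
      message(sprintf("%s: AHI %.1f, %d epochs, %.1f%% positive",
                      p$subject_id, gen$truth$true_ahi, nrow(tbl),
                      100 * mean(tbl$label == "RE_positive")))
    }
    list(epochs = tbl,
         subject = tibble::tibble(subject_id = p$subject_id,
                                  ahi = gen$truth$true_ahi,
                                  n_epochs = nrow(tbl)))
  })
  list(epochs = dplyr::bind_rows(lapply(per_subject, `[[`, "epochs")),
       subjects = dplyr::bind_rows(lapply(per_subject, `[[`, "subject")))
}
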