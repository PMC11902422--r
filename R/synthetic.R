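# Synthetic 8-channel dumbbell-curl sEMG generator.
#
# Emulates the standard acquisition design: standing alternating dumbbell
# curls, 1 s flexion + 1 s extension per arm, alternating for six cycles
# (one alternating cycle lasts 4-5 s, so a six-cycle trial is ~24-30 s),
# sampled at 1000 Hz on 8 channels. The left arm moves first; the right arm
# starts half a cycle later. Channels of the same arm share burst timing
# with channel-specific amplitude factors. Ground-truth burst intervals are
# returned alongside every recording.

# Relative amplitude of the non-biceps muscles of an arm (biceps, triceps,
# brachioradialis, flexor carpi). Biceps dominates an elbow curl.
.channel_base_factors <- c(biceps = 1.0, triceps = 0.55,
                           brachiorad = 0.7, flexcarp = 0.5)

#' Create a synthetic subject profile
#'
#' A profile fixes the per-subject burst properties used by
#' [generate_trial()]: burst amplitude relative to the baseline-noise
#' standard deviation, burst duration, spectral centre of the burst noise,
#' and the coefficient of variation of per-burst amplitude jitter.
#'
#' @param subject_id Character label.
#' @param group `"amateur"` or `"professional"`.
#' @param burst_amplitude_scale Peak burst envelope amplitude in units of
#'   the baseline noise standard deviation (unitless). 0 produces a
#'   baseline-only recording whose ground-truth intervals are flagged
#'   sub-threshold.
#' @param burst_duration_s Burst duration in seconds (one curl: flexion
#'   followed by extension of one arm).
#' @param median_freq_hz Spectral centre of the burst noise; must lie
#'   strictly inside the 20-250 Hz pass band.
#' @param amplitude_jitter_cv Coefficient of variation of per-burst
#'   amplitude jitter (>= 0).
#' @param duration_jitter_s Standard deviation (s) of per-burst duration
#'   jitter around `burst_duration_s`.
#' @param median_freq_jitter_hz Standard deviation (Hz) of per-burst
#'   spectral-centre jitter around `median_freq_hz`.
#' @param gain Per-subject recording gain multiplying the whole signal
#'   (baseline noise and bursts alike, emulating electrode/skin coupling
#'   and amplifier differences; removed by amplitude normalization).
#' @param seed Integer seed for per-channel gain perturbations.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group = c("amateur", "professional"),
                            burst_amplitude_scale = 20,
                            burst_duration_s = 1.8,
                            median_freq_hz = 80,
                            amplitude_jitter_cv = 0.05,
                            duration_jitter_s = 0.15,
                            median_freq_jitter_hz = 8,
                            gain = 1,
                            seed = 1L) {
  group <- match.arg(group)
  stopifnot_scalar_num(burst_amplitude_scale, "burst_amplitude_scale")
  if (burst_amplitude_scale < 0)
    stop("`burst_amplitude_scale` must be >= 0", call. = FALSE)
  stopifnot_scalar_num(burst_duration_s, "burst_duration_s", positive = TRUE)
  stopifnot_scalar_num(median_freq_hz, "median_freq_hz")
  if (median_freq_hz <= 20 || median_freq_hz >= 250)
    stop("`median_freq_hz` must lie strictly inside (20, 250) Hz", call. = FALSE)
  stopifnot_scalar_num(amplitude_jitter_cv, "amplitude_jitter_cv")
  if (amplitude_jitter_cv < 0)
    stop("`amplitude_jitter_cv` must be >= 0", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), group = group,
         burst_amplitude_scale = burst_amplitude_scale,
         burst_duration_s = burst_duration_s,
         median_freq_hz = median_freq_hz,
         amplitude_jitter_cv = amplitude_jitter_cv,
         duration_jitter_s = duration_jitter_s,
         median_freq_jitter_hz = median_freq_jitter_hz,
         gain = gain,
         seed = as.integer(seed)),
    class = "subject_profile")
}

# Two-lobe raised-cosine envelope: a high peak (flexion) followed by a lower
# peak (extension). The lobes overlap so the inter-lobe dip stays above
# ~0.65 of the main peak, which keeps one curl from being split in two by
# the detector's end threshold.
burst_envelope <- function(n) {
  if (n < 4) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  hann <- function(u) ifelse(u >= 0 & u <= 1, sin(pi * u)^2, 0)
  lobe1 <- hann(t / 0.65)
  lobe2 <- 0.6 * hann((t - 0.35) / 0.65)
  lobe1 + lobe2
}

# Band-limited unit-variance noise centred on f0 (Hz), soft-limited at
# sat sigma (tanh compression, as a preamplifier's limited range would).
# The soft limit pins the peak amplitude of a burst near sat * envelope,
# so the per-subject normalization divisor (the max over a subject's
# epochs) is stable rather than driven by Gaussian extremes.
burst_noise <- function(n, fs, f0, half_width = 35, sat = 2.2) {
  lo <- max(21, f0 - half_width)
  hi <- min(249, f0 + half_width)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  pad <- 200
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  sat * tanh(x / (sat * stats::sd(x)))
}

#' Generate one synthetic curl trial
#'
#' Produces an 8-channel recording of `n_cycles` alternating curls with the
#' left arm leading and the right arm offset by half a cycle, plus the
#' ground-truth burst intervals per channel. Bursts are band-limited
#' Gaussian noise centred on the profile's median frequency, shaped by a
#' two-lobe envelope, superposed on unit-variance baseline noise and a slow
#' sub-band drift (removed by the band-pass preprocessing).
#'
#' @param profile A [subject_profile()].
#' @param fs Sampling rate in Hz (> 500).
#' @param n_cycles Number of alternating curl cycles (>= 1).
#' @param trial_seed Integer seed; identical profile and seed give
#'   bit-identical recordings.
#' @param trial_id Label stored on the recording.
#' @return A list with elements `recording` (class `semg_recording`) and
#'   `truth` (class `trial_truth`: per-channel list of
#'   `(start_sample, end_sample)` interval matrices, arm assignment, and a
#'   `sub_threshold` flag).
#' @export
generate_trial <- function(profile, fs = 1000, n_cycles = 6, trial_seed = 1L,
                           trial_id = "T1") {
  if (!inherits(profile, "subject_profile"))
    stop("`profile` must be a subject_profile", call. = FALSE)
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (fs <= 2 * 250)
    stop("`fs` must exceed 500 Hz (Nyquist above the 250 Hz band edge)",
         call. = FALSE)
  stopifnot_scalar_num(n_cycles, "n_cycles", positive = TRUE, integerish = TRUE)

  layout <- channel_layout()
  with_seed(trial_seed, {
    lead_in <- 1.0
    lead_out <- 1.0
    cycle_len <- stats::runif(n_cycles, 4, 5)
    n_total <- ceiling((lead_in + sum(cycle_len) + lead_out) * fs)
    # per-burst duration jitter (bounded away from the detector's minimum
    # epoch length and from the half-cycle gap)
    draw_dur <- function(k) {
      d <- profile$burst_duration_s +
        stats::rnorm(k, 0, profile$duration_jitter_s)
      round(pmin(pmax(d, 1.3), 2.3) * fs)
    }
    left_dur <- draw_dur(n_cycles)
    right_dur <- draw_dur(n_cycles)

    cycle_start <- lead_in + c(0, cumsum(cycle_len[-n_cycles]))
    left_start <- round((cycle_start + stats::runif(n_cycles, 0, 0.1)) * fs) + 1L
    right_start <- round((cycle_start + cycle_len / 2 +
                          stats::runif(n_cycles, 0, 0.1)) * fs) + 1L
    left_iv <- cbind(start = left_start, end = pmin(left_start + left_dur - 1L, n_total))
    right_iv <- cbind(start = right_start, end = pmin(right_start + right_dur - 1L, n_total))

    # muscle amplitude factors (burst-to-noise, per channel) and
    # per-channel recording gains (whole-signal, per subject)
    ch_factors <- stats::setNames(
      rep(.channel_base_factors, 2),
      c(layout$left, layout$right)[c(1, 2, 3, 4, 5, 6, 8, 7)])
    # order above: left biceps/triceps/brachiorad/flexcarp = C1 C2 C5 C6,
    # right = C3 C4 C8 C7
    ch_gains <- with_seed(profile$seed, {
      g <- profile$gain * exp(stats::rnorm(8, 0, 0.1) - 0.1^2 / 2)
      stats::setNames(g, layout$channels)
    })

    samples <- matrix(0, nrow = n_total, ncol = 8,
                      dimnames = list(NULL, layout$channels))
    drift_phase <- stats::runif(8, 0, 2 * pi)
    tsec <- seq_len(n_total) / fs
    for (j in seq_len(8)) {
      samples[, j] <- stats::rnorm(n_total) +
        0.8 * sin(2 * pi * 0.4 * tsec + drift_phase[j])
    }

    cv <- profile$amplitude_jitter_cv
    sdlog <- sqrt(log(1 + cv^2))
    add_bursts <- function(iv, chans) {
      for (k in seq_len(nrow(iv))) {
        n_b <- iv[k, "end"] - iv[k, "start"] + 1L
        env <- burst_envelope(n_b)
        # spectral-centre jitter is shared by the channels of the arm
        # (one movement), noise realizations are channel-specific
        f0 <- min(240, max(30, profile$median_freq_hz +
                             stats::rnorm(1, 0, profile$median_freq_jitter_hz)))
        for (ch in chans) {
          jit <- if (cv > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
          core <- burst_noise(n_b, fs, f0)
          amp <- profile$burst_amplitude_scale * ch_factors[[ch]] * jit
          idx <- iv[k, "start"]:iv[k, "end"]
          samples[idx, ch] <- samples[idx, ch] + amp * env * core
        }
      }
      samples
    }
    samples <- add_bursts(left_iv, layout$left)
    samples <- add_bursts(right_iv, layout$right)
    samples <- sweep(samples, 2, ch_gains[colnames(samples)], `*`)

    intervals <- c(
      stats::setNames(rep(list(left_iv), 4), layout$left),
      stats::setNames(rep(list(right_iv), 4), layout$right)
    )[layout$channels]

    rec <- new_recording(samples, fs = fs, subject_id = profile$subject_id,
                         group = profile$group, trial_id = trial_id)
    truth <- structure(
      list(intervals = intervals,
           arm = list(left = layout$left, right = layout$right),
           n_cycles = n_cycles,
           sub_threshold = profile$burst_amplitude_scale == 0),
      class = "trial_truth")
    list(recording = rec, truth = truth)
  })
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject profiles around group baselines, with the professional
#' group differing from the amateur group exactly by `class_effects`, and
#' generates `n_trials` trials per subject. All randomness derives from
#' `seed`; the per-subject jitter distributions are recorded in the returned
#' metadata.
#'
#' @param n_amateur,n_professional Subjects per group (>= 1).
#' @param class_effects List with `amplitude_ratio`,
#'   `median_freq_shift_hz`, `duration_ratio`: professional baseline =
#'   amateur baseline scaled/shifted by these. Identity effects
#'   (`ratio 1, shift 0`) make the two groups exchangeable.
#' @param n_trials Trials per subject (>= 1).
#' @param n_cycles Alternating curl cycles per trial.
#' @param fs Sampling rate (Hz).
#' @param seed Root integer seed.
#' @param base Amateur-group baseline parameters (amplitude scale, median
#'   frequency Hz, burst duration s, per-burst amplitude jitter cv).
#' @return A list of class `semg_cohort`: `trials` (each a
#'   `list(recording, truth)`), `profiles` (data frame of realized subject
#'   parameters), `class_effects`, `jitter` (the jitter distributions
#'   used), and `seed`.
#' @export
generate_cohort <- function(n_amateur = 5, n_professional = 5,
                            class_effects = list(amplitude_ratio = 1.5,
                                                 median_freq_shift_hz = 15,
                                                 duration_ratio = 1),
                            n_trials = 5, n_cycles = 6, fs = 1000, seed = 1L,
                            base = list(amplitude_scale = 20,
                                        median_freq_hz = 80,
                                        burst_duration_s = 1.8,
                                        amplitude_jitter_cv = 0.05)) {
  for (nm in c("n_amateur", "n_professional", "n_trials", "n_cycles"))
    stopifnot_scalar_num(get(nm), nm, positive = TRUE, integerish = TRUE)
  eff <- utils::modifyList(list(amplitude_ratio = 1, median_freq_shift_hz = 0,
                                duration_ratio = 1), as.list(class_effects))

  groups <- c(rep("amateur", n_amateur), rep("professional", n_professional))
  subj_ids <- sprintf("S%02d", seq_along(groups))

  # Per-subject jitter around the group baseline (recorded in metadata).
  # Deliberately smaller than the per-burst jitter inside a subject, so a
  # single epoch carries little persistent subject signature.
  jitter <- list(snr = "lognormal(cv = 0.05)",
                 gain = "lognormal(cv = 0.3)",
                 median_freq = "normal(sd = 0.5 Hz)",
                 duration = "normal(sd = 0.01 s)",
                 per_burst = list(amplitude = "lognormal(cv = 0.05)",
                                  median_freq = "normal(sd = 8 Hz)",
                                  duration = "normal(sd = 0.15 s)"))

  profiles <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    amp0 <- base$amplitude_scale *
      (if (g == "professional") eff$amplitude_ratio else 1)
    mf0 <- base$median_freq_hz +
      (if (g == "professional") eff$median_freq_shift_hz else 0)
    dur0 <- base$burst_duration_s *
      (if (g == "professional") eff$duration_ratio else 1)
    prof <- with_seed(derive_seed(seed, "profile", i), {
      sdl_snr <- sqrt(log(1 + 0.05^2))
      sdl_gain <- sqrt(log(1 + 0.3^2))
      subject_profile(
        subject_id = subj_ids[i], group = g,
        burst_amplitude_scale = amp0 * stats::rlnorm(1, -sdl_snr^2 / 2, sdl_snr),
        median_freq_hz = min(240, max(30, mf0 + stats::rnorm(1, 0, 0.5))),
        burst_duration_s = max(1.3, dur0 + stats::rnorm(1, 0, 0.01)),
        amplitude_jitter_cv = base$amplitude_jitter_cv,
        gain = stats::rlnorm(1, -sdl_gain^2 / 2, sdl_gain),
        seed = derive_seed(seed, "channels", i))
    })
    profiles[[i]] <- prof
  }

  trials <- list()
  for (i in seq_along(profiles)) {
    for (tr in seq_len(n_trials)) {
      trials[[length(trials) + 1L]] <- generate_trial(
        profiles[[i]], fs = fs, n_cycles = n_cycles,
        trial_seed = derive_seed(seed, "trial", i, tr),
        trial_id = sprintf("T%d", tr))
    }
  }

  prof_df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, group = p$group,
               burst_amplitude_scale = p$burst_amplitude_scale,
               median_freq_hz = p$median_freq_hz,
               burst_duration_s = p$burst_duration_s,
               amplitude_jitter_cv = p$amplitude_jitter_cv,
               gain = p$gain,
               stringsAsFactors = FALSE)))

  structure(list(trials = trials, profiles = prof_df,
                 class_effects = eff, jitter = jitter, seed = seed),
            class = "semg_cohort")
}
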