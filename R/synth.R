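# Synthetic multimodal cohort generator. All randomness flows through one
# integer seed split into fixed per-channel substreams, so a given
# (profile, duration, seed) triple is bit-reproducible.

SYNTH_FS <- 1000L

# Table 1-style labels for the emotionally challenging quest events the
# annotations draw from (events 16-20 of the scenario's final quest).
EVENT_LABELS <- c("maxson_order", "quinlan_confirm", "haylen_hideout",
                  "danse_confrontation", "maxson_verdict")

substream <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + k * 1009) %% 2147483647)
}

with_substream <- function(seed, k, expr) {
  set.seed(substream(seed, k))
  force(expr)
}

# Gaussian-bump ECG template: P-QRS-T morphology with amplitude 1 at R.
ecg_template <- function(t_rel) {
  0.12 * exp(-((t_rel + 0.19) / 0.025)^2 / 2) -
    0.15 * exp(-((t_rel + 0.026) / 0.010)^2 / 2) +
    1.00 * exp(-(t_rel / 0.012)^2 / 2) -
    0.25 * exp(-((t_rel - 0.030) / 0.010)^2 / 2) +
    0.30 * exp(-((t_rel - 0.25) / 0.05)^2 / 2)
}

# Canonical bi-exponential SCR kernel (rise 0.75 s, decay 2.0 s), peak 1.
scr_kernel <- function(fs, span = 10) {
  t <- seq(0, span, by = 1 / fs)
  k <- exp(-t / 2.0) - exp(-t / 0.75)
  k / max(k)
}

unit_var <- function(x) {
  s <- sd(x)
  if (s == 0) x else x / s
}

# Event layout: the emotionally challenging quest occupies the later part of
# the session; four event intervals jointly cover >= 60% of the recording.
make_event_table <- function(duration, seed) {
  set.seed(substream(seed, 7L))
  starts <- c(0.260, 0.455, 0.645, 0.835)
  ends <- c(0.435, 0.625, 0.815, 0.995)
  jit <- runif(8, -0.008, 0.008)
  starts <- pmax(0, starts + jit[1:4])
  ends <- pmin(1, ends + jit[5:8])
  labels <- sample(EVENT_LABELS, 4)
  data.frame(
    event_id = paste0("ev", seq_along(starts)),
    label = labels,
    start_s = round(starts * duration, 3),
    end_s = round(ends * duration, 3),
    stringsAsFactors = FALSE
  )
}

#' Generate one synthetic five-channel physiological recording
#'
#' Simulates a 1000 Hz recording of ECG, EDA, respiration, EMG and skin
#' temperature for one participant drawn from a [condition_profile()],
#' together with the ground truth (true R-peak times, SCR event times,
#' breath onsets and the event annotation table) against which detectors
#' and feature extractors can be scored.
#'
#' Channel models: ECG places a fixed P-QRS-T Gaussian template at beat
#' times from an integrate-and-fire process (mean RR = 60/heart rate,
#' beat-to-beat jitter `rr_within_sd`) over low-frequency baseline wander
#' and white noise; EDA is a slow tonic drift plus bi-exponential phasic
#' responses at Poisson times; respiration is a quasi-sinusoid with
#' breath-wise period and depth jitter; EMG is zero-mean shaped noise whose
#' spectral mass splits at 1 Hz per `emg_fine_fraction` and whose in-event
#' variance is scaled by `emg_event_contrast`; temperature is a bounded
#' ramp of height `temp_offset` plus a slow random walk.
#'
#' @param profile A [condition_profile()].
#' @param duration Recording length in seconds (>= 60).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param participant_id Identifier stored in the recording.
#' @return A list with elements `recording` (class `mm_recording`: fields
#'   `participant_id`, `condition`, `fs`, `duration`, `channels` with
#'   `ecg`, `eda`, `rsp`, `emg`, `temp`) and `ground_truth` (fields
#'   `r_peak_times`, `scr_event_times`, `breath_boundaries`, `events`,
#'   `heart_rate`, `channel_seeds`).
#' @export
generate_recording <- function(profile, duration, seed,
                               participant_id = "p01") {
  validate_profile(profile)
  if (!is.numeric(duration) || duration < 60) {
    stop("invalid duration: must be a number >= 60 seconds")
  }
  fs <- SYNTH_FS
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  events <- make_event_table(duration, seed)

  # participant-level draws ------------------------------------------------
  set.seed(substream(seed, 8L))
  hr <- max(30, rnorm(1, profile$hr_mean, profile$hr_between_sd))
  depth <- max(0.3, rnorm(1, profile$resp_depth_mean,
                          profile$resp_depth_between_sd))
  scr_rate <- profile$scr_rate *
    exp(rnorm(1, -profile$scr_rate_log_sd^2 / 2, profile$scr_rate_log_sd))
  fine_frac <- min(0.999, max(0.5, rnorm(1, profile$emg_fine_fraction,
                                         profile$emg_fine_between_sd)))

  # ECG ---------------------------------------------------------------------
  set.seed(substream(seed, 1L))
  mean_rr <- 60 / hr
  beats <- numeric(0)
  tt <- mean_rr / 2
  while (tt < duration) {
    beats <- c(beats, tt)
    tt <- tt + max(0.25, rnorm(1, mean_rr, profile$rr_within_sd))
  }
  amps <- pmax(0.2, 1 + rnorm(length(beats), 0, profile$r_amp_jitter))
  set.seed(substream(seed, 2L))
  ecg <- 0.20 * sin(2 * pi * 0.18 * t + runif(1, 0, 2 * pi)) +
    0.10 * sin(2 * pi * 0.33 * t + runif(1, 0, 2 * pi)) +
    rnorm(n, 0, 0.03)
  half <- as.integer(0.35 * fs)
  tpl_t <- (-half:half) / fs
  tpl <- ecg_template(tpl_t)
  for (i in seq_along(beats)) {
    c0 <- as.integer(round(beats[i] * fs)) + 1L
    idx <- (c0 - half):(c0 + half)
    keep <- idx >= 1L & idx <= n
    ecg[idx[keep]] <- ecg[idx[keep]] + amps[i] * tpl[keep]
  }

  # EDA ---------------------------------------------------------------------
  set.seed(substream(seed, 3L))
  # tonic drift sits well below the 0.02 Hz phasic cut-off
  tonic <- 2 + 0.5 * sin(2 * pi * t / 150 + runif(1, 0, 2 * pi)) +
    0.3 * sin(2 * pi * t / 95 + runif(1, 0, 2 * pi))
  n_scr <- rpois(1, scr_rate / 60 * duration)
  scr_times <- sort(runif(n_scr, 0, max(0, duration - 2)))
  eda <- tonic + rnorm(n, 0, 0.01)
  if (n_scr > 0) {
    kern <- scr_kernel(fs)
    scr_amps <- rlnorm(n_scr, log(profile$scr_amp_mean) - 0.4^2 / 2, 0.4)
    for (i in seq_len(n_scr)) {
      i0 <- as.integer(round(scr_times[i] * fs)) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      eda[idx] <- eda[idx] + scr_amps[i] * kern[seq_along(idx)]
    }
  }

  # RSP ---------------------------------------------------------------------
  set.seed(substream(seed, 4L))
  onsets <- numeric(0)
  periods <- numeric(0)
  depths <- numeric(0)
  b <- runif(1, 0, profile$resp_period_mean / 2)
  while (b < duration) {
    p <- max(1.5, rnorm(1, profile$resp_period_mean,
                        profile$resp_period_jitter))
    onsets <- c(onsets, b)
    periods <- c(periods, p)
    depths <- c(depths, max(0.2, rnorm(1, depth, 0.1 * depth)))
    b <- b + p
  }
  rsp <- rnorm(n, 0, 0.25)
  for (j in seq_along(onsets)) {
    i0 <- as.integer(floor(onsets[j] * fs)) + 1L
    i1 <- min(n, as.integer(floor((onsets[j] + periods[j]) * fs)))
    if (i0 > n) break
    seg_t <- t[i0:i1] - onsets[j]
    rsp[i0:i1] <- rsp[i0:i1] +
      (depths[j] / 2) * sin(2 * pi * seg_t / periods[j])
  }

  # EMG ---------------------------------------------------------------------
  set.seed(substream(seed, 5L))
  low <- unit_var(signal::filtfilt(signal::butter(2, 1 / (fs / 2), "low"),
                                   rnorm(n)))
  high <- unit_var(signal::filtfilt(signal::butter(2, c(1, 14) / (fs / 2),
                                                   "pass"), rnorm(n)))
  u <- sqrt(1 - fine_frac) * low + sqrt(fine_frac) * high
  mask <- rep(1, n)
  for (j in seq_len(nrow(events))) {
    i0 <- as.integer(round(events$start_s[j] * fs)) + 1L
    i1 <- min(n, as.integer(round(events$end_s[j] * fs)))
    mask[i0:i1] <- sqrt(profile$emg_event_contrast)
  }
  emg <- profile$emg_total_energy_scale * mask * u

  # TEMP --------------------------------------------------------------------
  set.seed(substream(seed, 6L))
  ramp <- pmin(t / (0.3 * duration), 1)
  steps <- rnorm(ceiling(duration) + 1L, 0, profile$temp_drift_sd)
  walk <- approx(x = 0:ceiling(duration), y = cumsum(steps), xout = t)$y
  temp <- profile$temp_offset * ramp + walk + rnorm(n, 0, 0.002)

  # signals are quantized to 1e-6 units (far below every noise floor) so
  # that the plain-text signal files round-trip bit-exactly
  rec <- structure(list(
    participant_id = participant_id,
    condition = profile$label,
    fs = fs,
    duration = n / fs,
    channels = lapply(list(ecg = ecg, eda = eda, rsp = rsp, emg = emg,
                           temp = temp), round, digits = 6)
  ), class = "mm_recording")

  gt <- list(
    r_peak_times = beats,
    r_peak_amps = amps,
    scr_event_times = scr_times,
    breath_boundaries = onsets,
    events = events,
    heart_rate = hr,
    channel_seeds = vapply(1:8, function(k) substream(seed, k), integer(1))
  )
  list(recording = rec, ground_truth = gt)
}

#' @export
print.mm_recording <- function(x, ...) {
  cat("<mm_recording>", x$participant_id, sprintf("(%s)", x$condition),
      "-", sprintf("%.1f s @ %d Hz,", x$duration, x$fs),
      paste(names(x$channels), collapse = "/"), "\n")
  invisible(x)
}

#' Simulate a two-condition cohort in memory
#'
#' Generates `n_per_group` participants per condition without touching the
#' file system. Participant seeds are derived deterministically from `seed`.
#'
#' @inheritParams generate_cohort
#' @return A list of per-participant entries, each with `recording`,
#'   `ground_truth` and `annotation` (the event table).
#' @export
simulate_cohort <- function(play_profile = default_profiles()$play,
                            watch_profile = default_profiles()$watch,
                            n_per_group = 14, duration = 300, seed = 17) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  profs <- list(play_profile, watch_profile)
  out <- list()
  idx <- 0L
  for (g in 1:2) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", c("play", "watch")[g], i)
      r <- generate_recording(profs[[g]], duration,
                              seed = substream(seed, 100L + idx),
                              participant_id = pid)
      out[[pid]] <- list(recording = r$recording,
                         ground_truth = r$ground_truth,
                         annotation = r$ground_truth$events)
    }
  }
  out
}

#' Generate a cohort and write it to disk
#'
#' Writes one signal CSV (`time_s,ecg,eda,rsp,emg,temp`) and one annotation
#' TSV (`event_id`, `label`, `start_s`, `end_s`) per participant, plus a
#' cohort manifest CSV. The default cohort has 14 participants per
#' condition with the narrative endings split 12:2 within each condition.
#'
#' @param out_dir Output directory (created if missing).
#' @param play_profile,watch_profile [condition_profile()]s for the active
#'   and passive condition.
#' @param n_per_group Participants per condition (>= 2).
#' @param duration Recording length in seconds.
#' @param seed Integer master seed.
#' @return The manifest as a data.frame (columns `participant_id`,
#'   `condition`, `ending`, `recording_path`, `annotation_path`),
#'   invisibly also written to `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(out_dir,
                            play_profile = default_profiles()$play,
                            watch_profile = default_profiles()$watch,
                            n_per_group = 14, duration = 300, seed = 17) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  cohort <- simulate_cohort(play_profile, watch_profile, n_per_group,
                            duration, seed)
  # ending allocation: 12:2 proportion within each condition
  n_exec <- max(1L, round(n_per_group * 2 / 14))
  if (n_per_group < 3) n_exec <- 0L
  rows <- lapply(names(cohort), function(pid) {
    entry <- cohort[[pid]]
    rec_path <- file.path(out_dir, paste0(pid, "_signals.csv"))
    ann_path <- file.path(out_dir, paste0(pid, "_events.tsv"))
    write_recording(entry$recording, rec_path)
    write_annotation(entry$annotation, ann_path)
    i <- as.integer(sub("^[a-z]+", "", pid))
    data.frame(participant_id = pid,
               condition = entry$recording$condition,
               ending = if (i <= n_per_group - n_exec) "spare" else "execute",
               recording_path = rec_path,
               annotation_path = ann_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}
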