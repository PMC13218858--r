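# Per-modality signal conditioning and fiducial detection. Processing order
# for every channel is: per-participant z-score over the full recording,
# then filtering, then detection. All filters are zero-phase (forward-
# backward) 2nd-order Butterworth, which preserves fiducial timing.

#' Z-score a signal (population SD)
#'
#' Centres to mean 0 and scales to SD 1 using the population (1/n)
#' standard deviation. Constant input maps to all zeros rather than
#' erroring, so degenerate windows propagate as zero vectors.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("zscore requires at least 2 samples")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - m) / s
}

#' Remove ECG baseline drift with a two-stage median filter
#'
#' The baseline estimate is a cascade of running medians of width 200 ms
#' then 600 ms; the narrow QRS complex (well under 200 ms) passes through
#' untouched while respiration- and movement-scale drift is subtracted.
#'
#' @param ecg Numeric ECG, ideally z-scored.
#' @param fs Sampling rate in Hz.
#' @return Baseline-corrected signal of the same length.
#' @export
ecg_remove_baseline <- function(ecg, fs = 1000) {
  w1 <- 2L * as.integer(0.2 * fs / 2) + 1L   # 200 ms, odd
  w2 <- 2L * as.integer(0.6 * fs / 2) + 1L   # 600 ms, odd
  if (length(ecg) <= w2) stop("ECG too short for 600 ms median filter")
  baseline <- runmed(runmed(ecg, w1), w2)
  ecg - as.numeric(baseline)
}

butter_filtfilt <- function(x, w, type) {
  bf <- signal::butter(2, w, type)
  # remove the mean before filtering: the forward-backward pass starts
  # from zero state, so a DC offset would otherwise leave long edge
  # transients; low-pass filters get the mean restored afterwards
  m <- mean(x)
  y <- signal::filtfilt(bf, x - m)
  if (type == "low") y + m else y
}

#' High-pass filter EDA at 0.02 Hz
#'
#' Zero-phase 2nd-order Butterworth; removes tonic baseline drift so that
#' only phasic activity remains.
#'
#' @param eda Numeric EDA signal.
#' @param fs Sampling rate in Hz.
#' @return Filtered signal.
#' @export
eda_highpass <- function(eda, fs = 1000) {
  if (length(eda) < 10 * fs) stop("EDA too short: need at least 10 s")
  butter_filtfilt(eda, 0.02 / (fs / 2), "high")
}

#' Band-pass filter respiration at 0.1-5 Hz
#'
#' @param rsp Numeric respiration signal.
#' @param fs Sampling rate in Hz.
#' @return Filtered signal.
#' @export
rsp_bandpass <- function(rsp, fs = 1000) {
  if (length(rsp) < 10 * fs) stop("RSP too short: need at least 10 s")
  butter_filtfilt(rsp, c(0.1, 5) / (fs / 2), "pass")
}

moving_average <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Pan-Tompkins QRS detection
#'
#' Classic stage chain: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150 ms moving-window integration, adaptive dual thresholds
#' with a 200 ms refractory period and search-back at half threshold when
#' an expected beat is missed. Each detection is refined to the local
#' maximum of the input ECG within +/-50 ms.
#'
#' @param ecg Baseline-removed, z-scored ECG.
#' @param fs Sampling rate in Hz.
#' @return An `rr_series`: list with `r_peak_times` (s), `r_amplitudes`
#'   (input signal value at each peak) and `rr_intervals` (s).
#' @export
pan_tompkins <- function(ecg, fs = 1000) {
  n <- length(ecg)
  if (n < 2 * fs) stop("insufficient beats: ECG shorter than 2 s")
  bp <- butter_filtfilt(ecg, c(5, 15) / (fs / 2), "pass")
  der <- as.numeric(stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2))
  der[is.na(der)] <- 0
  sq <- der^2
  w <- as.integer(0.15 * fs)
  mwi <- moving_average(sq, w)
  mwi[is.na(mwi)] <- 0

  refractory <- as.integer(0.2 * fs)
  cand <- local_maxima(mwi)
  # enforce minimum candidate spacing: keep the larger of close pairs
  if (length(cand) > 1) {
    keep <- logical(length(cand))
    last <- 1L
    keep[1] <- TRUE
    for (i in 2:length(cand)) {
      if (cand[i] - cand[last] >= refractory) {
        keep[i] <- TRUE
        last <- i
      } else if (mwi[cand[i]] > mwi[cand[last]]) {
        keep[last] <- FALSE
        keep[i] <- TRUE
        last <- i
      }
    }
    cand <- cand[keep]
  }
  if (length(cand) == 0) stop("insufficient beats: no QRS candidates found")

  init <- mwi[seq_len(min(n, 2L * fs))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_hist <- numeric(0)
  for (i in seq_along(cand)) {
    k <- cand[i]
    v <- mwi[k]
    if (v > thr1) {
      peaks <- c(peaks, k)
      spki <- 0.125 * v + 0.875 * spki
      if (length(peaks) > 1) {
        rr_hist <- c(rr_hist, (k - peaks[length(peaks) - 1]) / fs)
        if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
      }
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: accept a sub-threshold candidate at half threshold if
      # the expected beat interval has elapsed
      if (length(peaks) > 0 && length(rr_hist) > 0) {
        if ((k - peaks[length(peaks)]) / fs > 1.66 * mean(rr_hist) &&
            v > 0.5 * thr1) {
          peaks <- c(peaks, k)
          spki <- 0.25 * v + 0.75 * spki
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) < 2) stop("insufficient beats: fewer than 2 detections")

  # refine to the local ECG maximum within +/-50 ms
  hw <- as.integer(0.05 * fs)
  refined <- vapply(peaks, function(k) {
    lo <- max(1L, k - hw)
    hi <- min(n, k + hw)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # drop residual double detections inside the refractory window
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) >= refractory)
    while (!all(keep)) {
      refined <- refined[keep]
      keep <- c(TRUE, diff(refined) >= refractory)
    }
  }
  if (length(refined) < 2) stop("insufficient beats: fewer than 2 detections")
  times <- (refined - 1) / fs
  structure(list(
    r_peak_times = times,
    r_amplitudes = ecg[refined],
    rr_intervals = diff(times)
  ), class = "rr_series")
}

#' Detect respiratory cycles on a filtered respiration signal
#'
#' Cycles are delimited at inspiration onsets (upward zero crossings of the
#' lightly smoothed signal). A candidate cycle is accepted only if its
#' exhaled excursion (peak minus following trough) reaches `exhale_frac`
#' of the running median excursion over the preceding candidates, which
#' suppresses spurious shallow cycles.
#'
#' @param rsp_filtered Band-passed respiration signal.
#' @param fs Sampling rate in Hz.
#' @param exhale_frac Acceptance threshold as a fraction of the running
#'   median exhaled excursion (default 0.65).
#' @return A `breath_series`: list with `onsets` (s), `depth`
#'   (peak-to-trough), `period` (onset-to-onset, s) and `duty`
#'   (inhale time / period). Zero accepted cycles gives empty vectors.
#' @export
detect_breaths <- function(rsp_filtered, fs = 1000, exhale_frac = 0.65) {
  n <- length(rsp_filtered)
  empty <- structure(list(onsets = numeric(0), depth = numeric(0),
                          period = numeric(0), duty = numeric(0)),
                     class = "breath_series")
  if (n < fs) return(empty)
  hw <- as.integer(0.15 * fs)
  w <- max(3L, 2L * hw + 1L)  # ~300 ms smoothing
  x <- moving_average(rsp_filtered, w)
  x[is.na(x)] <- 0
  up <- which(x[-n] <= 0 & x[-1] > 0) + 1L
  if (length(up) < 2) return(empty)
  # refine each onset back to the raw upward zero crossing, which the
  # smoothing edge can displace by up to half the smoothing window
  up <- vapply(up, function(i0) {
    j <- i0
    lim <- max(1L, i0 - hw)
    while (j > lim && rsp_filtered[j - 1L] > 0) j <- j - 1L
    j
  }, integer(1))
  up <- unique(up)
  onsets <- numeric(0)
  depth <- numeric(0)
  period <- numeric(0)
  duty <- numeric(0)
  excursions <- numeric(0)
  for (j in seq_along(up)) {
    i0 <- up[j]
    i1 <- if (j < length(up)) up[j + 1] else n
    if (i1 - i0 < as.integer(0.2 * fs)) next
    seg <- x[i0:i1]
    pk <- which.max(seg)
    tr_rel <- if (pk < length(seg)) pk + which.min(seg[pk:length(seg)]) - 1L else pk
    exc <- seg[pk] - seg[tr_rel]
    if (exc <= 0) next
    med <- if (length(excursions) > 0) {
      median(utils::tail(excursions, 10))
    } else {
      NA_real_
    }
    excursions <- c(excursions, exc)
    if (!is.na(med) && exc < exhale_frac * med) next
    onsets <- c(onsets, (i0 - 1) / fs)
    depth <- c(depth, exc)
    period <- c(period, (i1 - i0) / fs)
    duty <- c(duty, (pk - 1) / (i1 - i0))
  }
  structure(list(onsets = onsets, depth = depth, period = period,
                 duty = duty), class = "breath_series")
}

#' Down-sample EMG to 32 Hz
#'
#' Anti-alias low-pass at 16 Hz (zero-phase 2nd-order Butterworth), then
#' resample on the exact 32 Hz grid `k/32` s by linear interpolation.
#' Output length is `floor(length(emg) * 32 / fs)`.
#'
#' @param emg Numeric EMG signal.
#' @param fs Input sampling rate in Hz.
#' @return Numeric vector sampled at 32 Hz.
#' @export
emg_downsample <- function(emg, fs = 1000) {
  n <- length(emg)
  if (n < fs) stop("EMG too short: need at least 1 s")
  lp <- butter_filtfilt(emg, 16 / (fs / 2), "low")
  m <- as.integer(floor(n * 32 / fs))
  t_in <- (seq_len(n) - 1) / fs
  t_out <- (seq_len(m) - 1) / 32
  approx(t_in, lp, xout = t_out, rule = 2)$y
}

#' Condition all five channels of a recording
#'
#' Applies the full per-modality chain: z-score each channel over the
#' whole recording, then baseline-remove and Pan-Tompkins-detect the ECG,
#' high-pass the EDA, band-pass the respiration and detect breath cycles,
#' and decimate the EMG to 32 Hz. Temperature is z-scored only.
#'
#' @param rec An `mm_recording`.
#' @param exhale_frac Breath-cycle acceptance threshold, see
#'   [detect_breaths()].
#' @return A list with `rr` (an `rr_series`), `breaths` (a
#'   `breath_series`), `ecg_clean`, `eda_hp`, `rsp_filt`, `emg32`,
#'   `temp_z`, plus `fs` and `duration`.
#' @export
preprocess_recording <- function(rec, exhale_frac = 0.65) {
  stopifnot(inherits(rec, "mm_recording"))
  fs <- rec$fs
  ecg_z <- zscore(rec$channels$ecg)
  ecg_clean <- ecg_remove_baseline(ecg_z, fs)
  rr <- pan_tompkins(ecg_clean, fs)
  eda_hp <- eda_highpass(zscore(rec$channels$eda), fs)
  rsp_filt <- rsp_bandpass(zscore(rec$channels$rsp), fs)
  breaths <- detect_breaths(rsp_filt, fs, exhale_frac)
  emg32 <- emg_downsample(zscore(rec$channels$emg), fs)
  list(rr = rr, breaths = breaths, ecg_clean = ecg_clean, eda_hp = eda_hp,
       rsp_filt = rsp_filt, emg32 = emg32,
       temp_z = zscore(rec$channels$temp),
       fs = fs, duration = rec$duration)
}
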