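# Windowing and the canonical 80-feature inventory across the five
# modalities: 31 ECG + 12 RSP + 8 TEMP + 12 EDA + 17 EMG. Dropping EMG
# leaves 63 features; dropping EMG and EDA leaves 51.

ECG_FEATURES <- c(
  "RR mean", "RR std", "RR mad", "RR median", "RR min", "RR max", "bpm",
  "RRdiff mean", "RRdiff std", "RRdiff mad", "RMSSD", "pNN20", "pNN50",
  "R mean", "R std", "R mad", "Rdiff mean", "Rdiff std",
  "pwr VLF", "pwr LF", "pwr HF", "pwr TP",
  "psd VLF", "psd LF", "psd HF", "psd TP",
  "LF/HF ratio", "LF norm", "HF norm", "peak-freq LF", "peak-freq HF"
)
RSP_FEATURES <- c(
  "val mean", "val std", "val mad", "prd mean", "prd std", "prd mad",
  "Diffval mean", "Diffval std", "Diffprd mean", "Diffprd std",
  "breath rate", "duty ratio"
)
TEMP_FEATURES <- c(
  "temp mean", "temp std", "temp mad", "temp min", "temp max",
  "temp Diff mean", "temp Diff std", "temp Diff mad"
)
EDA_FEATURES <- as.vector(t(outer(c("LF", "HF", "VHF"),
                                  c("time sam", "frq sam", "frq pwr",
                                    "frq psd"), paste)))
EMG_FEATURES <- c(
  "Total Eng",
  paste(c(paste0("d", 1:6), "a6"), "Eng"),
  paste0(c(paste0("d", 1:6), "a6"), " Eng%"),
  "1–2 level Eng%", "5–6 level (7) Eng%"
)

#' The canonical feature inventory
#'
#' `feature_names()` returns the 80 canonical feature names in extraction
#' order; `feature_modalities()` maps each name to its modality
#' (`ECG`, `RSP`, `TEMP`, `EDA`, `EMG`); `feature_set()` returns the names
#' belonging to a named ablation set.
#'
#' @return Character vector of length 80 (`feature_names`), a named
#'   character vector (`feature_modalities`), or a subset of names
#'   (`feature_set`).
#' @export
feature_names <- function() {
  c(ECG_FEATURES, RSP_FEATURES, TEMP_FEATURES, EDA_FEATURES, EMG_FEATURES)
}

#' @rdname feature_names
#' @export
feature_modalities <- function() {
  setNames(
    rep(c("ECG", "RSP", "TEMP", "EDA", "EMG"),
        times = c(length(ECG_FEATURES), length(RSP_FEATURES),
                  length(TEMP_FEATURES), length(EDA_FEATURES),
                  length(EMG_FEATURES))),
    feature_names()
  )
}

#' @rdname feature_names
#' @param set One of `"full"`, `"wo_emg"`, `"wo_emg_eda"`.
#' @export
feature_set <- function(set = c("full", "wo_emg", "wo_emg_eda")) {
  set <- match.arg(set)
  mods <- feature_modalities()
  drop <- switch(set, full = character(0), wo_emg = "EMG",
                 wo_emg_eda = c("EMG", "EDA"))
  names(mods)[!mods %in% drop]
}

#' Windowing and band/threshold configuration
#'
#' @param width,offset Window width and offset in seconds. The defaults
#'   (10 s / 10 s) give consecutive non-overlapping windows.
#' @return A `window_spec` list.
#' @export
window_spec <- function(width = 10, offset = 10) {
  if (width <= 0 || offset <= 0) stop("window width and offset must be > 0")
  structure(list(width = width, offset = offset), class = "window_spec")
}

#' @rdname window_spec
#' @param theta_t Prominence threshold (z-units) for counting time-domain
#'   EDA events ("time sam").
#' @param theta_f Relative power threshold for counting active spectral
#'   bins ("frq sam").
#' @param exhale_frac Breath-cycle acceptance threshold.
#' @param eda_fs Working rate (Hz) for windowed EDA band analysis.
#' @export
feature_config <- function(theta_t = 0.05, theta_f = 0.1,
                           exhale_frac = 0.65, eda_fs = 20) {
  list(
    theta_t = theta_t, theta_f = theta_f, exhale_frac = exhale_frac,
    eda_fs = eda_fs,
    # HRV spectrum: RR tachogram resampled at 8 Hz, 32 s frame, 256-point
    # FFT (bin width 1/32 Hz); bands in Hz.
    tacho_fs = 8, frame_s = 32,
    ecg_bands = list(VLF = c(0, 0.04), LF = c(0.04, 0.15), HF = c(0.15, 0.4)),
    eda_bands = list(LF = c(0.02, 0.5), HF = c(0.5, 1), VHF = c(1, Inf))
  )
}

#' Consecutive non-overlapping windows inside an event segment
#'
#' Windows are `[k*offset, k*offset + width)` seconds from the segment
#' start, kept only if they fit entirely inside the segment (the
#' incomplete tail is dropped).
#'
#' @param segment An `event_segment` (or any list with `start_s`/`end_s`).
#' @param spec A [window_spec()].
#' @return Data frame with `window_index` (0-based), absolute `start_s`
#'   and `end_s`; zero rows if the segment is shorter than one window.
#' @export
make_windows <- function(segment, spec = window_spec()) {
  dur <- segment$end_s - segment$start_s
  k <- 0:max(0, ceiling(dur / spec$offset))
  starts <- segment$start_s + k * spec$offset
  keep <- starts + spec$width <= segment$end_s + 1e-9
  data.frame(window_index = k[keep], start_s = starts[keep],
             end_s = starts[keep] + spec$width)
}

mad_raw <- function(x) median(abs(x - median(x)))

#' Time-domain HRV features for one window
#'
#' Statistics of the RR intervals between beats falling in the window,
#' their first differences, and the R-peak amplitudes. `bpm` is the mean
#' over beats of 60/RR (which exceeds 60 / mean RR unless RR is constant).
#'
#' @param rr An `rr_series` from [pan_tompkins()].
#' @param window Numeric `c(start_s, end_s)`.
#' @return Named numeric vector of the 18 time-domain ECG features; all
#'   `NA` when fewer than 3 beats fall in the window.
#' @export
ecg_time_features <- function(rr, window) {
  nm <- ECG_FEATURES[1:18]
  out <- setNames(rep(NA_real_, length(nm)), nm)
  inw <- rr$r_peak_times >= window[1] & rr$r_peak_times < window[2]
  if (sum(inw) < 3) return(out)
  amps <- rr$r_amplitudes[inw]
  ivals <- diff(rr$r_peak_times[inw])
  d <- diff(ivals)
  out["RR mean"] <- mean(ivals)
  out["RR std"] <- sd(ivals)
  out["RR mad"] <- mad_raw(ivals)
  out["RR median"] <- median(ivals)
  out["RR min"] <- min(ivals)
  out["RR max"] <- max(ivals)
  out["bpm"] <- mean(60 / ivals)
  out["RRdiff mean"] <- mean(d)
  out["RRdiff std"] <- sd(d)
  out["RRdiff mad"] <- mad_raw(d)
  out["RMSSD"] <- sqrt(mean(d^2))
  out["pNN20"] <- mean(abs(d) > 0.020)
  out["pNN50"] <- mean(abs(d) > 0.050)
  out["R mean"] <- mean(amps)
  out["R std"] <- sd(amps)
  out["R mad"] <- mad_raw(amps)
  out["Rdiff mean"] <- mean(diff(amps))
  out["Rdiff std"] <- sd(diff(amps))
  out
}

#' Frequency-domain HRV features for one window
#'
#' The RR tachogram (each interval placed at the time of its closing beat)
#' inside a 32-s frame centred on the window and clipped to the event is
#' resampled to 8 Hz by cubic spline, mean-removed, zero-padded to 256
#' samples and Fourier transformed (bin width 1/32 Hz). Band power is the
#' one-sided sum of squared spectral magnitudes; PSD is power divided by
#' bandwidth; total power is the sum over VLF, LF and HF.
#'
#' @param rr An `rr_series`.
#' @param window Numeric `c(start_s, end_s)`.
#' @param event_bounds Numeric `c(start_s, end_s)` of the enclosing event;
#'   the frame is clipped to it.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of the 13 spectral ECG features; all `NA`
#'   when the clipped frame holds under 16 s of RR coverage.
#' @export
ecg_freq_features <- function(rr, window, event_bounds = window,
                              cfg = feature_config()) {
  nm <- ECG_FEATURES[19:31]
  out <- setNames(rep(NA_real_, length(nm)), nm)
  centre <- mean(window)
  half <- cfg$frame_s / 2
  f0 <- max(event_bounds[1], centre - half)
  f1 <- min(event_bounds[2], centre + half)
  tt <- rr$r_peak_times[-1]
  vv <- rr$rr_intervals
  inf <- tt >= f0 & tt <= f1
  if (sum(inf) < 4) return(out)
  tt <- tt[inf]
  vv <- vv[inf]
  if (max(tt) - min(tt) < cfg$frame_s / 2) return(out)
  grid <- seq(f0, f1, by = 1 / cfg$tacho_fs)
  grid <- grid[grid >= min(tt) & grid <= max(tt)]
  if (length(grid) < cfg$tacho_fs * cfg$frame_s / 2) return(out)
  tach <- splinefun(tt, vv, method = "natural")(grid)
  tach <- tach - mean(tach)
  nfft <- cfg$tacho_fs * cfg$frame_s
  padded <- c(tach, rep(0, nfft - length(tach)))[1:nfft]
  spec <- fft(padded)
  k <- seq_len(nfft / 2)
  freqs <- k / cfg$frame_s
  p <- (2 / nfft^2) * Mod(spec[k + 1])^2
  bandpow <- function(b) sum(p[freqs > b[1] & freqs <= b[2]])
  pv <- bandpow(cfg$ecg_bands$VLF)
  pl <- bandpow(cfg$ecg_bands$LF)
  ph <- bandpow(cfg$ecg_bands$HF)
  out["pwr VLF"] <- pv
  out["pwr LF"] <- pl
  out["pwr HF"] <- ph
  out["pwr TP"] <- pv + pl + ph
  bw <- vapply(cfg$ecg_bands, function(b) b[2] - b[1], numeric(1))
  out["psd VLF"] <- pv / bw["VLF"]
  out["psd LF"] <- pl / bw["LF"]
  out["psd HF"] <- ph / bw["HF"]
  out["psd TP"] <- (pv + pl + ph) / sum(bw)
  out["LF/HF ratio"] <- if (ph > 0) pl / ph else NA_real_
  out["LF norm"] <- if (pl + ph > 0) pl / (pl + ph) else NA_real_
  out["HF norm"] <- if (pl + ph > 0) ph / (pl + ph) else NA_real_
  pk <- function(b) {
    sel <- which(freqs > b[1] & freqs <= b[2])
    if (length(sel) == 0 || all(p[sel] == 0)) return(NA_real_)
    freqs[sel[which.max(p[sel])]]
  }
  out["peak-freq LF"] <- pk(cfg$ecg_bands$LF)
  out["peak-freq HF"] <- pk(cfg$ecg_bands$HF)
  out
}

#' Respiratory features for one window
#'
#' Statistics of per-cycle depth (`val`) and period (`prd`) for cycles
#' whose inspiration onset falls in the window, their first differences,
#' the breath rate (60 / mean period, breaths per minute), and the mean
#' duty ratio (inhale time / period).
#'
#' @param breaths A `breath_series` from [detect_breaths()].
#' @param window Numeric `c(start_s, end_s)`.
#' @return Named numeric vector of the 12 respiratory features; all `NA`
#'   when fewer than 2 cycles start in the window.
#' @export
rsp_features <- function(breaths, window) {
  out <- setNames(rep(NA_real_, length(RSP_FEATURES)), RSP_FEATURES)
  inw <- breaths$onsets >= window[1] & breaths$onsets < window[2]
  if (sum(inw) < 2) return(out)
  val <- breaths$depth[inw]
  prd <- breaths$period[inw]
  out["val mean"] <- mean(val)
  out["val std"] <- sd(val)
  out["val mad"] <- mad_raw(val)
  out["prd mean"] <- mean(prd)
  out["prd std"] <- sd(prd)
  out["prd mad"] <- mad_raw(prd)
  out["Diffval mean"] <- mean(diff(val))
  out["Diffval std"] <- sd(diff(val))
  out["Diffprd mean"] <- mean(diff(prd))
  out["Diffprd std"] <- sd(diff(prd))
  out["breath rate"] <- 60 / mean(prd)
  out["duty ratio"] <- mean(breaths$duty[inw])
  out
}

#' Skin-temperature features for one window
#'
#' Amplitude statistics of the in-window samples and of their first-order
#' differences.
#'
#' @param temp Numeric vector of in-window (z-scored) temperature samples.
#' @return Named numeric vector of the 8 temperature features.
#' @export
temp_features <- function(temp) {
  out <- setNames(rep(NA_real_, length(TEMP_FEATURES)), TEMP_FEATURES)
  if (length(temp) < 2) return(out)
  d <- diff(temp)
  out["temp mean"] <- mean(temp)
  out["temp std"] <- sd(temp)
  out["temp mad"] <- mad_raw(temp)
  out["temp min"] <- min(temp)
  out["temp max"] <- max(temp)
  out["temp Diff mean"] <- mean(d)
  out["temp Diff std"] <- sd(d)
  out["temp Diff mad"] <- mad_raw(d)
  out
}

#' EMG wavelet-energy features for one 10-s window at 32 Hz
#'
#' A 6-level periodized db5 decomposition yields sub-bands d1 (8-16 Hz)
#' down to d6 (0.25-0.5 Hz) and the approximation a6 (0-0.25 Hz). Band
#' energy is the sum of squared coefficients; proportions are relative to
#' the (exactly conserved) total. Grouped features sum the proportions of
#' the two finest-time levels (d1+d2, i.e. 4-16 Hz) and of the slow levels
#' d5+d6+a6 (below 1 Hz).
#'
#' @param emg32 Numeric vector of 320 samples (10 s at 32 Hz).
#' @return Named numeric vector of the 17 EMG features; proportions are
#'   `NA` for a zero-energy window.
#' @export
emg_wavelet_features <- function(emg32) {
  out <- setNames(rep(NA_real_, length(EMG_FEATURES)), EMG_FEATURES)
  if (length(emg32) != 320) return(out)
  cf <- dwt_db5(emg32, 6)
  eng <- vapply(cf, function(v) sum(v^2), numeric(1))
  total <- sum(eng)
  bands <- c(paste0("d", 1:6), "a6")
  out["Total Eng"] <- total
  out[paste(bands, "Eng")] <- eng[bands]
  if (total > 0) {
    prop <- eng[bands] / total
    out[paste0(bands, " Eng%")] <- prop
    out["1–2 level Eng%"] <- prop["d1"] + prop["d2"]
    out["5–6 level (7) Eng%"] <- prop["d5"] + prop["d6"] + prop["a6"]
  }
  out
}

# Peaks of x with topographic prominence >= min_prom. The base on each
# side is the minimum between the peak and the nearest higher sample (or
# the signal edge); prominence is height above the higher of the two bases.
find_prominent_peaks <- function(x, min_prom) {
  pk <- local_maxima(x)
  if (length(pk) == 0) return(integer(0))
  n <- length(x)
  prom <- vapply(pk, function(i) {
    h <- x[i]
    j <- i - 1L
    base_l <- h
    while (j >= 1L && x[j] <= h) {
      if (x[j] < base_l) base_l <- x[j]
      j <- j - 1L
    }
    j <- i + 1L
    base_r <- h
    while (j <= n && x[j] <= h) {
      if (x[j] < base_r) base_r <- x[j]
      j <- j + 1L
    }
    h - max(base_l, base_r)
  }, numeric(1))
  pk[prom >= min_prom]
}

resample_linear <- function(x, fs_in, fs_out) {
  lp <- butter_filtfilt(x, (0.4 * fs_out) / (fs_in / 2), "low")
  m <- as.integer(floor(length(x) * fs_out / fs_in))
  approx((seq_along(x) - 1) / fs_in, lp,
         xout = (seq_len(m) - 1) / fs_out, rule = 2)$y
}

fft_bandlimit <- function(x, fs, lo, hi) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  spec <- fft(x)
  spec[!(freqs >= lo & freqs <= hi)] <- 0
  Re(fft(spec, inverse = TRUE)) / n
}

#' EDA band features for one window
#'
#' The high-pass-filtered window is decimated to a 20 Hz working rate and
#' analysed in three bands (LF 0.02-0.5 Hz, HF 0.5-1 Hz, VHF above 1 Hz).
#' Per band: `time sam` counts local maxima of the band-limited signal
#' with prominence at least `theta_t`; `frq sam` counts FFT bins whose
#' power exceeds `theta_f` times the band's maximum bin power; `frq pwr`
#' is the one-sided summed band power and `frq psd` that power per Hz of
#' bandwidth (the VHF bandwidth runs to the working Nyquist).
#'
#' @param eda_hp Full high-pass-filtered (z-scored) EDA signal.
#' @param window Numeric `c(start_s, end_s)`.
#' @param fs Sampling rate of `eda_hp`.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of the 12 EDA features (zero counts and
#'   powers for a flat window).
#' @export
eda_features <- function(eda_hp, window, fs = 1000, cfg = feature_config()) {
  out <- setNames(rep(0, length(EDA_FEATURES)), EDA_FEATURES)
  i0 <- as.integer(round(window[1] * fs)) + 1L
  i1 <- min(length(eda_hp), as.integer(round(window[2] * fs)))
  x <- eda_hp[i0:i1]
  if (length(x) < fs) return(out)
  xr <- resample_linear(x, fs, cfg$eda_fs)
  n <- length(xr)
  nyq <- cfg$eda_fs / 2
  spec <- fft(xr)
  k <- seq_len(floor(n / 2))
  freqs <- k * cfg$eda_fs / n
  p <- (2 / n^2) * Mod(spec[k + 1])^2
  for (b in names(cfg$eda_bands)) {
    lo <- cfg$eda_bands[[b]][1]
    hi <- min(cfg$eda_bands[[b]][2], nyq)
    xb <- fft_bandlimit(xr, cfg$eda_fs, lo, hi)
    out[paste(b, "time sam")] <-
      length(find_prominent_peaks(xb, cfg$theta_t))
    sel <- freqs >= lo & freqs <= hi
    pb <- p[sel]
    if (length(pb) > 0 && max(pb) > 0) {
      out[paste(b, "frq sam")] <- sum(pb > cfg$theta_f * max(pb))
    }
    out[paste(b, "frq pwr")] <- sum(pb)
    out[paste(b, "frq psd")] <- sum(pb) / (hi - lo)
  }
  out
}

window_features <- function(pre, window, event_bounds, cfg) {
  fs <- pre$fs
  i0 <- as.integer(round(window[1] * fs)) + 1L
  i1 <- min(length(pre$temp_z), as.integer(round(window[2] * fs)))
  t32 <- (seq_along(pre$emg32) - 1) / 32
  k32 <- which(t32 >= window[1] - 1e-9 & t32 < window[2] - 1e-9)
  emg_win <- if (length(k32) >= 320) pre$emg32[k32[1:320]] else numeric(0)
  c(
    ecg_time_features(pre$rr, window),
    ecg_freq_features(pre$rr, window, event_bounds, cfg),
    rsp_features(pre$breaths, window),
    temp_features(pre$temp_z[i0:i1]),
    eda_features(pre$eda_hp, window, fs, cfg),
    emg_wavelet_features(emg_win)
  )
}

#' Extract the 80-feature matrix for one recording
#'
#' Conditions the recording once, cuts the annotated events, and computes
#' the canonical 80 features in every complete 10-s window.
#'
#' @param rec An `mm_recording`.
#' @param annotation Event annotation data.frame.
#' @param spec A [window_spec()].
#' @param cfg A [feature_config()].
#' @return Data frame with `participant_id`, `condition`, `event_id`,
#'   `window_index` and one column per canonical feature.
#' @export
features_for_recording <- function(rec, annotation, spec = window_spec(),
                                   cfg = feature_config()) {
  pre <- preprocess_recording(rec, exhale_frac = cfg$exhale_frac)
  segments <- extract_events(rec, annotation)
  rows <- list()
  for (seg in segments) {
    wins <- make_windows(seg, spec)
    if (nrow(wins) == 0) next
    for (i in seq_len(nrow(wins))) {
      fv <- window_features(pre, c(wins$start_s[i], wins$end_s[i]),
                            c(seg$start_s, seg$end_s), cfg)
      rows[[length(rows) + 1L]] <- c(
        list(participant_id = rec$participant_id,
             condition = rec$condition,
             event_id = seg$event_id,
             window_index = wins$window_index[i]),
        as.list(fv)
      )
    }
  }
  if (length(rows) == 0) {
    return(empty_feature_matrix())
  }
  dt <- data.table::rbindlist(rows)
  data.table::setDF(dt)
  dt
}

empty_feature_matrix <- function() {
  cols <- c(list(participant_id = character(0), condition = character(0),
                 event_id = character(0), window_index = integer(0)),
            setNames(rep(list(numeric(0)), 80), feature_names()))
  as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Extract the window-level feature matrix for a whole cohort
#'
#' Iterates over the manifest, loading each participant's recording and
#' annotation and appending its window rows. Participants yielding zero
#' valid windows are excluded with a warning.
#'
#' @param manifest Manifest data.frame (or path to `manifest.csv`).
#' @param spec A [window_spec()].
#' @param cfg A [feature_config()].
#' @return Feature matrix with exactly 80 feature columns plus the label
#'   columns `participant_id`, `condition`, `event_id`, `window_index`.
#' @export
extract_feature_matrix <- function(manifest, spec = window_spec(),
                                   cfg = feature_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  parts <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- load_recording(manifest$recording_path[i],
                          participant_id = manifest$participant_id[i],
                          condition = manifest$condition[i])
    ann <- read_annotation(manifest$annotation_path[i])
    fm <- features_for_recording(rec, ann, spec, cfg)
    if (nrow(fm) == 0) {
      warning("participant ", manifest$participant_id[i],
              " produced no valid windows; excluded")
      next
    }
    parts[[length(parts) + 1L]] <- fm
  }
  if (length(parts) == 0) return(empty_feature_matrix())
  dt <- data.table::rbindlist(parts)
  data.table::setDF(dt)
  dt
}

#' Simulate a cohort and extract its feature matrix, streaming
#'
#' Equivalent to [simulate_cohort()] followed by
#' [extract_features_cohort()], but generates and conditions one
#' participant at a time so only the feature rows are retained. Intended
#' for repeated-cohort studies (calibration, direction recovery).
#'
#' @inheritParams simulate_cohort
#' @param spec A [window_spec()].
#' @param cfg A [feature_config()].
#' @return The window-level feature matrix.
#' @export
simulate_feature_matrix <- function(play_profile = default_profiles()$play,
                                    watch_profile = default_profiles()$watch,
                                    n_per_group = 14, duration = 300,
                                    seed = 17, spec = window_spec(),
                                    cfg = feature_config()) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  profs <- list(play_profile, watch_profile)
  parts <- list()
  idx <- 0L
  for (g in 1:2) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", c("play", "watch")[g], i)
      r <- generate_recording(profs[[g]], duration,
                              seed = substream(seed, 100L + idx),
                              participant_id = pid)
      fm <- features_for_recording(r$recording, r$ground_truth$events,
                                   spec, cfg)
      if (nrow(fm) > 0) parts[[length(parts) + 1L]] <- fm
    }
  }
  if (length(parts) == 0) return(empty_feature_matrix())
  dt <- data.table::rbindlist(parts)
  data.table::setDF(dt)
  dt
}

#' Extract features from an in-memory cohort
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @inheritParams extract_feature_matrix
#' @return The window-level feature matrix.
#' @export
extract_features_cohort <- function(cohort, spec = window_spec(),
                                    cfg = feature_config()) {
  parts <- lapply(cohort, function(entry) {
    features_for_recording(entry$recording, entry$annotation, spec, cfg)
  })
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (length(parts) == 0) return(empty_feature_matrix())
  dt <- data.table::rbindlist(parts)
  data.table::setDF(dt)
  dt
}
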