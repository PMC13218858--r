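test_that("the canonical inventory has the printed structure", {
  nm <- feature_names()
  expect_length(nm, 80)
  expect_false(anyDuplicated(nm) > 0)
  mods <- feature_modalities()
  counts <- vapply(c("ECG", "RSP", "TEMP", "EDA", "EMG"),
                   function(m) sum(mods == m), integer(1))
  expect_equal(unname(counts), c(31L, 12L, 8L, 12L, 17L))
  expect_length(feature_set("full"), 80)
  expect_length(feature_set("wo_emg"), 63)
  expect_length(feature_set("wo_emg_eda"), 51)
  # every feature reported in the group-difference and screening tables
  must_have <- c("bpm", "R std", "RR mean", "pwr TP", "psd TP", "psd VLF",
                 "pwr VLF", "R mad", "val mean", "Diffprd std",
                 "HF time sam", "HF frq sam", "HF frq pwr", "Total Eng",
                 "5–6 level (7) Eng%", "temp mean", "temp Diff std")
  expect_true(all(must_have %in% nm))
})

test_that("windowing drops incomplete tails", {
  seg <- list(start_s = 0, end_s = 50)
  expect_equal(nrow(make_windows(seg)), 5)
  expect_equal(nrow(make_windows(list(start_s = 0, end_s = 9.9))), 0)
  w <- make_windows(list(start_s = 0, end_s = 25))
  expect_equal(nrow(w), 2)
  expect_equal(w$start_s, c(0, 10))
  expect_equal(w$end_s, c(10, 20))
  # windows are relative to the segment start
  w2 <- make_windows(list(start_s = 7.5, end_s = 32.5))
  expect_equal(w2$start_s, c(7.5, 17.5))
})

test_that("time-domain HRV features match hand arithmetic", {
  rr <- rr_series(seq(0.5, 59.5, by = 1))
  f <- ecg_time_features(rr, c(0, 60))
  expect_equal(unname(f["RR mean"]), 1)
  expect_equal(unname(f["RR std"]), 0)
  expect_equal(unname(f["bpm"]), 60)
  expect_equal(unname(f["RMSSD"]), 0)
  expect_equal(unname(f["pNN50"]), 0)

  rr2 <- rr_series(c(0.1, 0.9, 1.9))
  f2 <- ecg_time_features(rr2, c(0, 10))
  expect_equal(unname(f2["RR mean"]), 0.9)
  expect_equal(unname(f2["bpm"]), (75 + 60) / 2)

  f3 <- ecg_time_features(rr_series(c(1, 2)), c(0, 10))
  expect_true(all(is.na(f3)))
})

test_that("bpm is never below 60 over mean RR (Jensen)", {
  set.seed(4)
  for (i in 1:20) {
    times <- cumsum(runif(30, 0.6, 1.2))
    f <- ecg_time_features(rr_series(times), c(0, max(times) + 1))
    expect_gte(f[["bpm"]], 60 / f[["RR mean"]] - 1e-12)
  }
  # equality iff RR constant
  f <- ecg_time_features(rr_series(seq(0, 10, by = 0.8)), c(0, 11))
  expect_equal(f[["bpm"]], 60 / f[["RR mean"]])
})

test_that("spectral HRV features localise a pure LF modulation", {
  # 0.1 Hz sinusoidal modulation of the RR series
  beats <- numeric(80)
  tt <- 0
  for (i in seq_along(beats)) {
    beats[i] <- tt
    tt <- tt + 0.8 + 0.05 * sin(2 * pi * 0.1 * tt)
  }
  rr <- rr_series(beats)
  f <- ecg_freq_features(rr, c(15, 25), event_bounds = c(0, max(beats)))
  expect_gte(f[["pwr LF"]] / f[["pwr TP"]], 0.9)
  expect_lt(abs(f[["peak-freq LF"]] - 0.1), 0.04)
  expect_equal(f[["pwr TP"]],
               f[["pwr VLF"]] + f[["pwr LF"]] + f[["pwr HF"]])
})

test_that("constant RR series carry no spectral power", {
  rr <- rr_series(seq(0.4, 60, by = 0.8))
  f <- ecg_freq_features(rr, c(20, 30), event_bounds = c(0, 60))
  expect_equal(unname(f["pwr TP"]), 0, tolerance = 1e-20)
})

test_that("insufficient RR coverage yields missing spectral features", {
  rr <- rr_series(seq(0, 5, by = 0.8))
  f <- ecg_freq_features(rr, c(0, 10), event_bounds = c(0, 10))
  expect_true(all(is.na(f)))
})

test_that("respiratory features match hand arithmetic", {
  br <- breath_series(onsets = c(1, 5, 9), depth = rep(2, 3),
                      period = rep(4, 3), duty = rep(0.25, 3))
  f <- rsp_features(br, c(0, 10))
  expect_equal(unname(f["val mean"]), 2)
  expect_equal(unname(f["prd mean"]), 4)
  expect_equal(unname(f["Diffprd std"]), 0)
  expect_equal(unname(f["breath rate"]), 15)
  expect_equal(unname(f["duty ratio"]), 0.25)

  br2 <- breath_series(onsets = c(0, 3, 7), depth = c(1, 1, 1),
                       period = c(3, 4, 5))
  f2 <- rsp_features(br2, c(0, 12))
  expect_equal(unname(f2["Diffprd mean"]), 1)
  expect_equal(unname(f2["Diffprd std"]), 0)
  expect_equal(unname(f2["prd mean"]), 4)

  one <- breath_series(2, 1.5, 4)
  expect_true(all(is.na(rsp_features(one, c(0, 10)))))
})

test_that("temperature features handle constants, ramps, and noise", {
  f <- temp_features(rep(0.7, 1000))
  expect_equal(unname(f["temp mean"]), 0.7)
  expect_equal(unname(f["temp std"]), 0)
  expect_equal(unname(f["temp Diff std"]), 0)

  ramp <- seq(0, 1, by = 1e-3)
  f2 <- temp_features(ramp)
  expect_equal(unname(f2["temp Diff mean"]), 1e-3)
  expect_equal(unname(f2["temp Diff std"]), 0)

  set.seed(8)
  x <- cumsum(rnorm(1000))
  f3 <- temp_features(x)
  expect_equal(unname(f3["temp mean"]), mean(x))
  expect_equal(unname(f3["temp std"]), sd(x))
  expect_equal(unname(f3["temp mad"]), median(abs(x - median(x))))
  expect_equal(unname(f3["temp min"]), min(x))
  expect_equal(unname(f3["temp Diff mad"]),
               median(abs(diff(x) - median(diff(x)))))
})

test_that("wavelet energies conserve window energy exactly", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(320)
    f <- emg_wavelet_features(x)
    expect_lt(abs(f[["Total Eng"]] - sum(x^2)) / sum(x^2), 1e-6)
    props <- f[paste0(c(paste0("d", 1:6), "a6"), " Eng%")]
    expect_equal(unname(sum(props)), 1, tolerance = 1e-9)
  }
})

test_that("wavelet sub-bands map frequency as expected", {
  # 10 Hz sits well inside d1 (8-16 Hz); a tone on the 8 Hz band edge
  # splits between d1 and d2 in any finite-length wavelet filter
  t <- (0:319) / 32
  f <- emg_wavelet_features(sin(2 * pi * 10 * t))
  props <- f[paste0(c(paste0("d", 1:6), "a6"), " Eng%")]
  expect_equal(names(which.max(props)), "d1 Eng%")
  slow <- emg_wavelet_features(sin(2 * pi * 0.4 * t))
  expect_gt(slow[["5–6 level (7) Eng%"]], 0.8)
})

test_that("zero-energy EMG windows yield missing proportions", {
  f <- emg_wavelet_features(rep(0, 320))
  expect_equal(unname(f["Total Eng"]), 0)
  expect_true(is.na(f[["d1 Eng%"]]))
  expect_true(is.na(f[["5–6 level (7) Eng%"]]))
})

test_that("dwt rejects lengths not divisible by 2^levels", {
  expect_error(dwt_db5(rnorm(300)), "divisible")
})

test_that("EDA features respond to phasic events and band content", {
  f0 <- eda_features(rep(0, 20000), c(0, 10))
  expect_true(all(f0 == 0))

  # trains of distinct SCR kernels: counts at least match the number
  # injected and grow monotonically while events remain separated
  kern <- exp(-(0:9999) / 2000) - exp(-(0:9999) / 750)
  kern <- kern / max(kern)
  counts <- vapply(c(1, 3, 5), function(k) {
    x <- rep(0, 10000)
    at <- round(seq(200, 8200, length.out = k))
    for (a in at) {
      idx <- a:min(10000, a + 3000)
      x[idx] <- x[idx] + 0.6 * kern[seq_along(idx)]
    }
    f <- eda_features(x, c(0, 10))
    f[["HF time sam"]] + f[["LF time sam"]]
  }, numeric(1))
  expect_gte(counts[3], 5)
  expect_true(all(diff(counts) > 0))

  t <- (0:9999) / 1000
  f7 <- eda_features(0.5 * sin(2 * pi * 0.7 * t), c(0, 10))
  expect_gt(f7[["HF frq pwr"]], f7[["LF frq pwr"]])
  expect_gt(f7[["HF frq pwr"]], f7[["VHF frq pwr"]])
})

test_that("mean phasic event counts rise with the generated SCR rate", {
  rates <- c(4, 8, 12, 16, 20)
  means <- vapply(seq_along(rates), function(i) {
    p <- default_profiles()$play
    p$scr_rate <- rates[i]
    p$scr_rate_log_sd <- 0
    r <- generate_recording(p, 120, seed = 300 + i)
    hp <- eda_highpass(zscore(r$recording$channels$eda), 1000)
    mean(vapply(0:11, function(w) {
      eda_features(hp, c(10 * w, 10 * w + 10))[["HF time sam"]]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(rates, means, method = "spearman"), 0.9)
})

test_that("feature extraction is invariant to a constant ECG offset", {
  r <- generate_recording(clean_profile(), 60, seed = 55)
  ann <- data.frame(event_id = "a", label = "x", start_s = 0, end_s = 60)
  f1 <- features_for_recording(r$recording, ann)
  r$recording$channels$ecg <- r$recording$channels$ecg + 42
  f2 <- features_for_recording(r$recording, ann)
  ecg_cols <- names(feature_modalities())[feature_modalities() == "ECG"]
  expect_equal(f1[, ecg_cols], f2[, ecg_cols], tolerance = 1e-8)
})

test_that("a fully annotated recording yields width/offset window counts", {
  r <- generate_recording(clean_profile(), 120, seed = 18)
  ann <- data.frame(event_id = "all", label = "x", start_s = 0, end_s = 120)
  fm <- features_for_recording(r$recording, ann)
  expect_equal(nrow(fm), 12)
  expect_equal(ncol(fm), 84)
  expect_identical(names(fm)[-(1:4)], feature_names())
})

test_that("the cohort extractor assembles labelled rows from files", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(dir, n_per_group = 2, duration = 120, seed = 44)
  fm <- extract_feature_matrix(man)
  expect_equal(ncol(fm), 84)
  expect_setequal(unique(fm$participant_id), man$participant_id)
  expect_setequal(unique(fm$condition), c("GamePlay", "GameWatch"))
  # in-memory and file routes agree
  fm2 <- simulate_feature_matrix(n_per_group = 2, duration = 120, seed = 44)
  expect_equal(fm, fm2, tolerance = 1e-6)
})
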