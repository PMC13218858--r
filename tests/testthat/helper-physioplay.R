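# Shared fixture builders. Everything is generated in code under fixed
# seeds; no fixture files are stored.

# metronomic heart, no between-participant spread: ground truth is exactly
# periodic, handy as a detector oracle
metronome_profile <- function(hr = 60) {
  condition_profile("GamePlay", hr_mean = hr, hr_between_sd = 0,
                    rr_within_sd = 0)
}

# default play profile with all between-participant spreads collapsed
clean_profile <- function(rr_within_sd = 0.05) {
  p <- default_profiles()$play
  p$hr_between_sd <- 0
  p$rr_within_sd <- rr_within_sd
  p
}

# GamePlay profile relabelled GameWatch: a true null condition pair
null_watch_profile <- function() {
  p <- default_profiles()$play
  p$label <- "GameWatch"
  p
}

# hand-built rr_series, bypassing detection
rr_series <- function(times, amps = rep(1, length(times))) {
  structure(list(r_peak_times = times, r_amplitudes = amps,
                 rr_intervals = diff(times)), class = "rr_series")
}

# hand-built breath_series
breath_series <- function(onsets, depth, period,
                          duty = rep(0.5, length(onsets))) {
  structure(list(onsets = onsets, depth = depth, period = period,
                 duty = duty), class = "breath_series")
}

# synthetic window-level feature matrix for classifier tests: n_per
# participants per condition, n_win windows each, iid noise features plus
# an optional perfectly informative one
toy_feature_matrix <- function(n_per = 10, n_win = 15, seed = 1,
                               informative = character(0)) {
  set.seed(seed)
  pids <- c(sprintf("play%02d", seq_len(n_per)),
            sprintf("watch%02d", seq_len(n_per)))
  cond <- rep(c("GamePlay", "GameWatch"), each = n_per)
  fm <- do.call(rbind, lapply(seq_along(pids), function(i) {
    data.frame(participant_id = pids[i], condition = cond[i],
               event_id = "ev1", window_index = seq_len(n_win) - 1L,
               stringsAsFactors = FALSE)
  }))
  for (f in feature_names()) {
    fm[[f]] <- rnorm(nrow(fm))
  }
  for (f in informative) {
    fm[[f]] <- ifelse(fm$condition == "GamePlay", 1, -1)
  }
  fm
}
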