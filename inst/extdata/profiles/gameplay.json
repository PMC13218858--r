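{
  "label": "GamePlay",
  "hr_mean": 78.09,
  "hr_between_sd": 5,
  "rr_within_sd": 0.04,
  "r_amp_jitter": 0.1,
  "resp_depth_mean": 1.05,
  "resp_depth_between_sd": 0.1,
  "resp_period_mean": 4,
  "resp_period_jitter": 0.55,
  "scr_rate": 20,
  "scr_amp_mean": 0.6,
  "scr_rate_log_sd": 0.2,
  "emg_total_energy_scale": 1,
  "emg_event_contrast": 0.75,
  "emg_fine_fraction": 0.94,
  "emg_fine_between_sd": 0.005,
  "temp_offset": 0.8,
  "temp_drift_sd": 0.01
}
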