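{
  "ctrl_w1118": {
    "class_label": "control",
    "gain": 10.0, "tf_peak_hz": 6.0, "tf_bandwidth_oct": 1.5,
    "sf_cutoff_cpd": 0.88, "low_sf_boost": 1.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "ctrl_w1": {
    "class_label": "control",
    "gain": 9.5, "tf_peak_hz": 5.8, "tf_bandwidth_oct": 1.5,
    "sf_cutoff_cpd": 0.85, "low_sf_boost": 1.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "ctrl_wDah": {
    "class_label": "control",
    "gain": 9.7, "tf_peak_hz": 5.9, "tf_bandwidth_oct": 1.5,
    "sf_cutoff_cpd": 0.86, "low_sf_boost": 1.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "ctrl_wTu": {
    "class_label": "control",
    "gain": 10.5, "tf_peak_hz": 6.2, "tf_bandwidth_oct": 1.4,
    "sf_cutoff_cpd": 0.95, "low_sf_boost": 1.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "pd_DJ1a": {
    "class_label": "early_PD",
    "gain": 12.0, "tf_peak_hz": 7.0, "tf_bandwidth_oct": 1.6,
    "sf_cutoff_cpd": 0.88, "low_sf_boost": 2.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "pd_DJ1b": {
    "class_label": "early_PD",
    "gain": 11.5, "tf_peak_hz": 6.8, "tf_bandwidth_oct": 1.5,
    "sf_cutoff_cpd": 0.80, "low_sf_boost": 1.8,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "pd_PINK1_B9": {
    "class_label": "early_PD",
    "gain": 13.0, "tf_peak_hz": 7.2, "tf_bandwidth_oct": 1.4,
    "sf_cutoff_cpd": 0.88, "low_sf_boost": 2.2,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "pd_PINK1_5": {
    "class_label": "early_PD",
    "gain": 12.5, "tf_peak_hz": 7.4, "tf_bandwidth_oct": 1.5,
    "sf_cutoff_cpd": 1.0, "low_sf_boost": 2.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "late_dLRRK": {
    "class_label": "late_PD",
    "gain": 10.0, "tf_peak_hz": 4.5, "tf_bandwidth_oct": 1.8,
    "sf_cutoff_cpd": 0.60, "low_sf_boost": 1.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  },
  "ndg_eggroll": {
    "class_label": "neurodegeneration",
    "gain": 9.8, "tf_peak_hz": 8.5, "tf_bandwidth_oct": 2.0,
    "sf_cutoff_cpd": 1.3, "low_sf_boost": 1.0,
    "fly_cv": 0.2, "noise_amp": 2.0, "noise_alpha": 1.0, "phase_2f": 0.7853981633974483
  }
}
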