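{
  "QEM1": {
    "rate_per_min": 10.2,
    "fixation_s": [4.9, 1.8],
    "decay_slope_deg_s": [0.32, 0.21],
    "peak_speed_deg_s": [849.1, 158.7],
    "amplitude_deg": [45, 5],
    "regularity": 0.8
  },
  "QEM2": {
    "rate_per_min": 1.6,
    "fixation_s": [7.3, 5.6],
    "decay_slope_deg_s": [0.89, 0.68],
    "peak_speed_deg_s": [849.1, 158.7],
    "amplitude_deg": [45, 5],
    "regularity": 0.1
  },
  "QEM3": {
    "rate_per_min": 1.8,
    "fixation_s": [9.7, 14.9],
    "decay_slope_deg_s": [0.03, 0.07],
    "peak_speed_deg_s": [849.1, 158.7],
    "amplitude_deg": [45, 5],
    "regularity": 0.1
  },
  "QNEM": {
    "rate_per_min": 0,
    "fixation_s": [0.001, 0],
    "decay_slope_deg_s": [0.001, 0],
    "peak_speed_deg_s": [849.1, 0],
    "amplitude_deg": [45, 0],
    "regularity": 0
  }
}
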