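[
  {
    "group_label": "control",
    "n_subjects": 16,
    "n_strides": 250,
    "phi1_mean": 0.4,
    "phi1_sd": 0.1,
    "phi2_mean": 0.1,
    "phi2_sd": 0.1,
    "stride_mean_s": 1.1,
    "stride_mean_sd_s": 0.1,
    "innovation_sd_s": 0.03,
    "trend_slope_s_per_stride": 0,
    "master_seed": 1
  },
  {
    "group_label": "huntington",
    "n_subjects": 20,
    "n_strides": 250,
    "phi1_mean": 0.1,
    "phi1_sd": 0.2,
    "phi2_mean": 0.0,
    "phi2_sd": 0.1,
    "stride_mean_s": 1.2,
    "stride_mean_sd_s": 0.2,
    "innovation_sd_s": 0.08,
    "trend_slope_s_per_stride": 0,
    "master_seed": 10001
  }
]
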