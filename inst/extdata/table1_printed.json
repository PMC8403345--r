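{
  "description": "Published reliability results of the 29-hip CT/MRI femoral torsion study; quantities as printed.",
  "icc": [
    {"comparison": "inter_modality", "stratum": "reader 1", "estimate": 0.950, "conf_low": 0.898, "conf_high": 0.976, "sem": 1.97},
    {"comparison": "inter_modality", "stratum": "reader 2", "estimate": 0.950, "conf_low": 0.897, "conf_high": 0.976, "sem": 1.92},
    {"comparison": "inter_reader", "stratum": "CT", "estimate": 0.957, "conf_low": 0.910, "conf_high": 0.979, "sem": 1.83},
    {"comparison": "inter_reader", "stratum": "MRI", "estimate": 0.945, "conf_low": 0.886, "conf_high": 0.973, "sem": 2.01}
  ],
  "difference": {"mean_diff": 0.42, "sd_diff": 2.77, "p_value": 0.253},
  "range": {"min": -16.4, "max": 28.2}
}
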