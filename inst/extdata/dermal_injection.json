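{
  "schema_version": 1,
  "label": "dermal_injection",
  "description": "Calibrated exogenous-TNC injection model for dermal fibroblasts: activation only at the 5 ug dose; irreversible at (km_feedback, v_feedback) = (5, 30), reversible at (10, 15).",
  "mode": "tnc_injection",
  "parameters": {
    "basal_Tw": 1,
    "basal_P": 0.10000000000000001,
    "basal_T": 0.10000000000000001,
    "vmax_dox": 0,
    "km_dox": 1,
    "n_dox": 1,
    "v_feedback": 30,
    "km_feedback": 5,
    "n_feedback": 4,
    "vmax_TwP": 10,
    "km_TwP": 5,
    "n_TwP": 2,
    "vmax_PT": 6,
    "km_PT": 5,
    "n_PT": 2,
    "deg_Tw": 1,
    "deg_P": 1,
    "deg_T": 1
  },
  "stimulus": {
    "dose_scale": 0.59999999999999998,
    "tnc_max": 3
  }
}
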