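{
  "schema_version": 1,
  "label": "mrc5",
  "description": "MRC5-like induction kinetics (identical to dox_reference): TNC 2-fold delay ~8 days under a dox step of level 10.",
  "mode": "dox",
  "parameters": {
    "basal_Tw": 1,
    "basal_P": 0.011111111111111112,
    "basal_T": 0.033333333333333333,
    "vmax_dox": 10,
    "km_dox": 8,
    "n_dox": 1,
    "v_feedback": 40,
    "km_feedback": 5,
    "n_feedback": 4,
    "vmax_TwP": 1.1111111111111112,
    "km_TwP": 5,
    "n_TwP": 4,
    "vmax_PT": 2,
    "km_PT": 9,
    "n_PT": 4,
    "deg_Tw": 1,
    "deg_P": 0.1111111111111111,
    "deg_T": 0.33333333333333331
  },
  "stimulus": {
    "dox_level": 10
  }
}
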