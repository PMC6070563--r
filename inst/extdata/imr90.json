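{
  "schema_version": 1,
  "label": "imr90",
  "description": "IMR90-like induction kinetics: same equilibria as dox_reference with faster Prrx1/TNC turnover; TNC 2-fold delay ~4 days.",
  "mode": "dox",
  "parameters": {
    "basal_Tw": 1,
    "basal_P": 0.028571428571428574,
    "basal_T": 0.066666666666666666,
    "vmax_dox": 10,
    "km_dox": 8,
    "n_dox": 1,
    "v_feedback": 40,
    "km_feedback": 5,
    "n_feedback": 4,
    "vmax_TwP": 2.8571428571428572,
    "km_TwP": 5,
    "n_TwP": 4,
    "vmax_PT": 4,
    "km_PT": 9,
    "n_PT": 4,
    "deg_Tw": 1,
    "deg_P": 0.2857142857142857,
    "deg_T": 0.66666666666666663
  },
  "stimulus": {
    "dox_level": 10
  }
}
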