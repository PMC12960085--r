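{
  "ve_cubic": {
    "coefficients": [-0.1918, 0.01515, -0.0001075, 0.0000003927],
    "names": ["V0", "V1", "V2", "V3"]
  },
  "age_linear": {
    "coefficients": [0.5916, 0.009138],
    "names": ["YIA", "SLA"]
  },
  "height_expgrowth": {
    "coefficients": [0.08766, 0.01293],
    "names": ["SLH", "KH"]
  },
  "weight_cubic": {
    "coefficients": [2.840, -0.1442, 0.002706, -0.00001486],
    "names": ["Wt0", "Wt1", "Wt2", "Wt3"]
  },
  "vo2peak_linear": {
    "coefficients": [0.1960, 0.1643],
    "names": ["PYI", "VO2SL"]
  },
  "hrmax_linear": {
    "coefficients": [1.392, -0.002975],
    "names": ["YIHR", "SLHR"]
  }
}
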