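{
  "kg_per_day": 0.40,
  "kk_per_day": 0.26,
  "v0_mm3": 27.0,
  "alpha_per_gy": 0.082,
  "gamma_per_kgy": 4.0,
  "a_ml_per_ug": 0.42,
  "b_ml_per_ug": 0.15,
  "alpha_beta_ratio_gy": 10
}
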