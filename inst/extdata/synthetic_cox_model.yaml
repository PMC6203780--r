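# Synthetic stand-in for a published Cox-model specification (fixture,
# not the published coefficients).
type: cox
baseline_survival: 0.9960
horizon: 5
terms:
  - {term: age, type: linear, coefficient: 0.060, reference: 55}
  - {term: sex, type: indicator, coefficient: 0.25, level: male}
  - {term: diabetes, type: linear, coefficient: 0.20}
  - {term: fh_category, type: indicator, coefficient: 0.55, level: '1'}
  - {term: fh_category, type: indicator, coefficient: 0.90, level: '2'}
  - {term: bmi, type: linear, coefficient: 0.020, reference: 27}
  - {term: smoking, type: linear, coefficient: 0.15}
  - {term: alcohol_g_day, type: linear, coefficient: 0.004}
  - {term: nsaid, type: linear, coefficient: -0.20}
  - {term: oestrogen, type: linear, coefficient: -0.10, sex: female}
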