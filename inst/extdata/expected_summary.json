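{
  "effective_dose_mSv": 13.362333333333333,
  "total_cancer_risk_per_million": 281.4,
  "genetic_effects_per_million": 348
}
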