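organ_name,w_t,risk_coefficient
Bladder,0.05,0.30
Bone marrow,0.12,0.50
Bone surface,0.01,0.05
Breast,0.05,0.20
Esophagus,0.05,0.30
Colon,0.12,0.85
Liver,0.05,0.15
Lung,0.12,0.85
Gonads,0.20,0.10
Skin,0.01,0.02
Stomach,0.12,1.10
Thyroid,0.05,0.08
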