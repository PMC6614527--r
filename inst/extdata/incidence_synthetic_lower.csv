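"band_label","rate_per_person_year","source_label"
"0-44",6e-05,"synthetic_lower"
"45-54",9e-04,"synthetic_lower"
"55-64",0.0017,"synthetic_lower"
"65-74",0.004,"synthetic_lower"
"75-84",0.009,"synthetic_lower"
"85+",0.015,"synthetic_lower"
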