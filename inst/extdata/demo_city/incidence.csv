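"band_label","rate_per_person_year","source_label"
"0-44",1e-04,"synthetic_higher"
"45-54",0.0015,"synthetic_higher"
"55-64",0.003,"synthetic_higher"
"65-74",0.007,"synthetic_higher"
"75-84",0.015,"synthetic_higher"
"85+",0.025,"synthetic_higher"
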