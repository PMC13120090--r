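age_start_y,age_end_y,mg_per_kg_week
0,0.25,0.1
0.25,0.5,0.2
0.5,0.75,0.4
0.75,50,0.8
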