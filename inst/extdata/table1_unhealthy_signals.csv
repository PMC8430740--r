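test_set,time_sequence,temperature_c,heart_rate_bpm,suspect
1,667,37.6,80,FALSE
1,668,37.4,68,FALSE
1,669,37.3,162,FALSE
1,670,37.7,168,FALSE
1,671,38,165,FALSE
1,672,37.7,169,FALSE
2,131,37.5,66,FALSE
2,132,37.7,70,FALSE
2,133,38,110,FALSE
2,134,37.9,100,FALSE
2,135,37.6,99,FALSE
2,601,37.7,89,FALSE
2,602,37.5,101,FALSE
2,603,37.3,65,FALSE
2,604,37.1,1140,TRUE
2,605,37,125,FALSE
2,606,37.8,110,FALSE
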