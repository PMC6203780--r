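age_lower	age_upper	rate
40	45	2e-4
45	50	3.5e-4
50	55	6e-4
55	60	9.5e-4
60	65	0.0014
65	70	0.0019
70	75	0.00245
75	80	0.003
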