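fh_category	rr
0	1
1	2.2
2	4
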