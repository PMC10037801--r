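	d1	d2	d3
d1	1	0.59999999999999998	0.20000000000000001
d2	0.59999999999999998	1	0.29999999999999999
d3	0.20000000000000001	0.29999999999999999	1
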