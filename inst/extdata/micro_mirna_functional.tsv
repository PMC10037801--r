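	m1	m2	m3	m4
m1	1	0.80000000000000004	0.20000000000000001	0.10000000000000001
m2	0.80000000000000004	1	0.29999999999999999	0.20000000000000001
m3	0.20000000000000001	0.29999999999999999	1	0.69999999999999996
m4	0.10000000000000001	0.20000000000000001	0.69999999999999996	1
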