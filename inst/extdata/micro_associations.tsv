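m1	d1
m1	d2
m2	d1
m3	d2
m3	d3
m4	d3
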