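>d1
d1	r
>d2
d2	r
>d3
d3	s
s	r
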