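base	A	G	U	C
A	33	50	32	36
G	60	60	20	42
U	22	33	62	44
C	36	38	47	60
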