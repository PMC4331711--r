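base	A	G	U	C
A	0.219	0.331	0.212	0.238
G	0.330	0.330	0.110	0.230
U	0.137	0.205	0.385	0.273
C	0.199	0.210	0.260	0.331
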