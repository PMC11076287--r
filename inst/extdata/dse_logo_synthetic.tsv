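A	C	G	T
0.05	0.05	0.30	0.60
0.10	0.05	0.25	0.60
0.05	0.05	0.15	0.75
0.05	0.05	0.40	0.50
0.08	0.07	0.25	0.60
0.10	0.10	0.20	0.60
0.05	0.05	0.60	0.30
0.05	0.15	0.20	0.60
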