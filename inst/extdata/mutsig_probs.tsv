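position	symbol	value
-2	A	0.28
-2	C	0.22
-2	G	0.22
-2	T	0.28
-1	A	0.2
-1	C	0.35
-1	G	0.2
-1	T	0.25
0	C>A	0.0025
0	C>G	0.0025
0	C>T	0.96
0	T>A	0.0025
0	T>C	0.03
0	T>G	0.0025
1	A	0.32
1	C	0.28
1	G	0.08
1	T	0.32
2	A	0.27
2	C	0.24
2	G	0.22
2	T	0.27
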