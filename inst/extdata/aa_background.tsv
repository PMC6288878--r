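symbol	prob
A	0.0826579
R	0.0553387
N	0.0406284
D	0.0546382
C	0.0137096
Q	0.0393275
E	0.0674472
G	0.0708496
H	0.0227159
I	0.0593415
L	0.0965676
K	0.0582408
M	0.0241169
F	0.038627
P	0.0472331
S	0.0660462
T	0.0535375
W	0.0110077
Y	0.0292205
V	0.0687481
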