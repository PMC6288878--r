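>SYN0001 synthetic_motif
A [ 30 10 75  5 40 25 ]
C [ 25  5  5  3 10 25 ]
G [ 25  5  5  2 10 25 ]
T [ 20 80 15 90 40 25 ]
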