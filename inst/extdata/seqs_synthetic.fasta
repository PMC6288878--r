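>s1
NASA
>s2
NGST
>s3
NAST
>s4
NTSA
>s5
NASA
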