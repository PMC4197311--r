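FAM1 s1 0 0 1 -9 A A G G
FAM1 s2 0 0 2 -9 A C 0 0
FAM1 s3 0 0 1 -9 C C G T
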