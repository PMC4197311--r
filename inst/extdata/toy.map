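1 rs1 0 100
2 rs2 0 500
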