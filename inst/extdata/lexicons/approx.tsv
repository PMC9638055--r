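couple	2
few	3
several	3
many	7
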