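G0004
G0005
G0013
G0021
G0029
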