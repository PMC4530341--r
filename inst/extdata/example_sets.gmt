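PLANTED_MODULE	synthetic: the planted module padded with extras	G0006	G0009	G0014	G0023	G0025	G0004	G0007	G0001	G0002
DECOY_A	synthetic: random decoy set	G0011	G0014	G0018	G0027	G0019	G0001	G0021	G0024
DECOY_B	synthetic: random decoy set	G0010	G0022	G0014	G0030	G0007	G0009	G0015	G0021
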