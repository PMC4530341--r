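sample_id	time	event
S0001	49.52	1
S0002	0.16	1
S0003	292.99	0
S0004	44.32	1
S0005	84.49	1
S0006	29.77	1
S0007	168.43	1
S0008	10.7	1
S0009	54.74	0
S0010	30.75	1
S0011	30.46	0
S0012	199.07	1
S0013	16.37	1
S0014	51.53	1
S0015	89.9	1
S0016	24.9	1
S0017	8.43	1
S0018	65.67	0
S0019	316.38	1
S0020	37.67	0
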