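G0001	pp	G0002
G0001	pp	G0003
G0001	pp	G0005
G0001	pp	G0006
G0001	pp	G0009
G0001	pp	G0012
G0001	pp	G0013
G0001	pp	G0015
G0001	pp	G0018
G0001	pp	G0020
G0001	pp	G0026
G0002	pp	G0003
G0002	pp	G0004
G0002	pp	G0005
G0002	pp	G0008
G0002	pp	G0010
G0002	pp	G0011
G0002	pp	G0015
G0002	pp	G0016
G0002	pp	G0017
G0002	pp	G0019
G0002	pp	G0022
G0002	pp	G0026
G0003	pp	G0004
G0003	pp	G0006
G0003	pp	G0007
G0003	pp	G0013
G0003	pp	G0014
G0003	pp	G0028
G0004	pp	G0008
G0004	pp	G0011
G0004	pp	G0014
G0004	pp	G0016
G0004	pp	G0017
G0004	pp	G0021
G0004	pp	G0024
G0004	pp	G0027
G0005	pp	G0012
G0006	pp	G0007
G0006	pp	G0009
G0006	pp	G0023
G0006	pp	G0025
G0007	pp	G0025
G0008	pp	G0010
G0008	pp	G0018
G0008	pp	G0021
G0008	pp	G0022
G0008	pp	G0028
G0012	pp	G0020
G0013	pp	G0029
G0014	pp	G0023
G0016	pp	G0019
G0019	pp	G0024
G0024	pp	G0027
G0024	pp	G0030
G0027	pp	G0029
G0028	pp	G0030
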