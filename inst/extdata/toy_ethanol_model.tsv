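#substrate	UPT
#product	EXE
#biomass	BIO
UPT	GLC_ext -> GLC	0	ptsG
FEM	GLC -> 2 ETH + 2 CO2	0	pfk,adhE
EXE	ETH -> ETH_ext	0	
EXC	CO2 -> CO2_ext	0	
BIO	GLC -> BM_ext	0	bio
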