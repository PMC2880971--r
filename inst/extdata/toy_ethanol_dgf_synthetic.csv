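metabolite,dGf_kcal_mol
GLC_ext,-219.22
GLC,-219.22
ETH,-43.39
CO2,-92.26
ETH_ext,-43.39
CO2_ext,-92.26
BM_ext,-219.5
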