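species,mw_g_per_mol
GLC_ext,180.156
ETH_ext,46.069
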