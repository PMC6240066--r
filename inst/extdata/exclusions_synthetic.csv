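species,reason
Manta birostris,manta ray: size hard to estimate visually; high biomass but rarely encountered
Myripristis berndti,nocturnal: daytime visual counts unreliable
Decapterus macarellus,pelagic schooling: transient schools inflate transect counts
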