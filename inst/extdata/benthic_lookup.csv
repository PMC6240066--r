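category,functional_group
hard_coral,coral
coral,coral
macroalgae,macroalgae
turf_algae,turf
turf,turf
cca,cca
crustose_coralline,cca
other,other_cover
sand,other_cover
rock,other_cover
sponge,other_cover
dead_coral,other_cover
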