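species,family,trophic,functional_group,a,b,typical_tl_cm,schooling
Naso unicornis,Acanthuridae,herbivore,browsers,0.0256,2.95,35,FALSE
Kyphosus cinerascens,Kyphosidae,herbivore,browsers,0.0181,3.02,30,TRUE
Acanthurus triostegus,Acanthuridae,herbivore,grazers,0.0282,2.90,18,TRUE
Ctenochaetus strigosus,Acanthuridae,herbivore,grazers,0.0309,2.92,14,FALSE
Chlorurus perspicillatus,Scaridae,herbivore,scrapers,0.0136,3.05,40,FALSE
Scarus psittacus,Scaridae,herbivore,scrapers,0.0155,3.00,22,TRUE
Caranx ignobilis,Carangidae,piscivore,predators,0.0231,2.96,70,FALSE
Aprion virescens,Lutjanidae,piscivore,predators,0.0132,3.01,55,FALSE
Parupeneus multifasciatus,Mullidae,invertivore,secondary,0.0148,3.04,22,FALSE
Chaetodon multicinctus,Chaetodontidae,corallivore,secondary,0.0257,2.98,10,FALSE
Abudefduf abdominalis,Pomacentridae,planktivore,secondary,0.0224,2.99,16,TRUE
Manta birostris,Mobulidae,planktivore,secondary,0.0105,3.10,300,FALSE
Myripristis berndti,Holocentridae,planktivore,secondary,0.0253,2.94,20,TRUE
Decapterus macarellus,Carangidae,planktivore,secondary,0.0089,3.08,25,TRUE
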