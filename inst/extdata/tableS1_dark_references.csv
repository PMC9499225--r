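subfamily,genus,species_group,species,brightness_mean,brightness_n,type_locality,relative_eye_size,role
Dolichoderinae,Dorymyrmex,NA,dark congeners (max of 5),NA,NA,NA,0.0249,dark_reference
Dolichoderinae,Iridomyrmex,NA,dark congeners (max of 5),NA,NA,NA,0.0278,dark_reference
Myrmicinae,Temnothorax,NA,dark congeners (max of 5),NA,NA,NA,0.0224,dark_reference
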