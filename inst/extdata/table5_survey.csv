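subfamily,genus,species_group,species,brightness_mean,brightness_n,type_locality,relative_eye_size,role
Dolichoderinae,Dorymyrmex,NA,ensifer,72.5,2,ARGENTINA,0.0331,candidate
Dolichoderinae,Dorymyrmex,NA,ensifer laevigatus,72.7,1,ARGENTINA,0.0323,candidate
Dolichoderinae,Dorymyrmex,NA,ensifer weiseri,72.0,1,ARGENTINA,0.0340,candidate
Dolichoderinae,Dorymyrmex,NA,exsanguinus,71.3,3,ARGENTINA,0.0370,candidate
Dolichoderinae,Dorymyrmex,NA,exsanguinus anaemicus,76.3,1,ARGENTINA,0.0384,candidate
Dolichoderinae,Dorymyrmex,NA,morenoi patagon,85.3,1,ARGENTINA,0.0344,candidate
Dolichoderinae,Dorymyrmex,NA,nr. morenoi,72.3,1,ARGENTINA,0.0383,candidate
Dolichoderinae,Iridomyrmex,NA,macrops,73.7,1,AUSTRALIA,0.0341,candidate
Myrmicinae,Temnothorax,laurae,arenarius,81.2,2,TUNISIA,0.0383,candidate
Myrmicinae,Temnothorax,laurae,arenarius fusciventris,78.7,1,TUNISIA,0.0353,candidate
Myrmicinae,Temnothorax,laurae,canescens,73.3,1,SPAIN,0.0246,candidate
Myrmicinae,Temnothorax,laurae,laciniatus,75.3,1,ALGERIA,0.0288,candidate
Myrmicinae,Temnothorax,laurae,laurae,72.7,1,TUNISIA,0.0273,candidate
Myrmicinae,Temnothorax,laurae,laurae rosae,77.0,1,TUNISIA,0.0314,candidate
Myrmicinae,Temnothorax,laurae,megalops,72.3,1,SUDAN,0.0267,candidate
Myrmicinae,Temnothorax,laurae,mpala,73.0,1,KENYA,0.0261,candidate
Myrmicinae,Temnothorax,laurae,naeviventris,73.4,3,TUNISIA,0.0330,candidate
Myrmicinae,Temnothorax,laurae,naeviventris kefensis,74.0,1,TUNISIA,0.0243,candidate
Myrmicinae,Temnothorax,tricarinatus,bestelmeyeri,75.0,1,USA,0.0303,candidate
Myrmicinae,Temnothorax,tricarinatus,coleenae,78.0,1,USA,0.0286,candidate
Myrmicinae,Temnothorax,tricarinatus,liebi,83.3,1,USA,0.0291,candidate
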