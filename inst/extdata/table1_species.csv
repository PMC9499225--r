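subfamily,genus,species,color_class,brightness_mean,brightness_se,brightness_n,activity,activity_class,eye_area_raw,eye_area_raw_se,facet_count_raw,facet_count_raw_se,D_raw,D_raw_se,mesosoma_mean,mesosoma_se,eye_area_emm,eye_area_emm_se,facet_count_emm,facet_count_emm_se,D_emm,D_emm_se,emm_covariate_eval_point
Formicinae,Myrmecocystus,christineae,pale,75.2,2.4,4,nocturnal,nocturnal,0.0763,0.0049,277.5,9.3,19.68,0.26,1.14,0.04,0.1196,0.0077,384.1,14.2,20.81,0.49,1.7434
Formicinae,Myrmecocystus,ewarti,pale,72.7,1.7,3,nocturnal,nocturnal,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,1.7434
Formicinae,Myrmecocystus,kennedyi,dark,55.9,0.2,3,diurnal,diurnal,0.0463,0.0025,322.8,11.3,13.71,0.22,1.43,0.04,0.0685,0.0058,377.6,10.7,14.29,0.37,1.7434
Formicinae,Myrmecocystus,mendax-03,dark,58.7,4.5,3,diurnal,diurnal,0.0817,0.0048,457.4,16.3,15.85,0.26,2.31,0.10,0.0413,0.0067,358.2,12.4,14.79,0.43,1.7434
Formicinae,Myrmecocystus,mexicanus-01,pale,73.8,1.1,4,nocturnal,nocturnal,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,1.7434
Formicinae,Myrmecocystus,mexicanus-02,pale,78.4,4.5,3,nocturnal,nocturnal,0.1609,0.0118,524.1,21.3,21.83,0.50,2.31,0.08,0.1207,0.0067,425.1,12.4,20.78,0.43,1.7434
Formicinae,Myrmecocystus,navajo,pale,74.1,2.8,6,"nocturnal, crepuscular in cooler months",nocturnal,0.1052,0.0068,349.8,14.5,20.27,0.37,1.67,0.07,0.1103,0.0052,352.3,9.6,20.41,0.33,1.7434
Formicinae,Myrmecocystus,testaceus,pale,72.3,1.7,3,nocturnal,nocturnal,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,1.7434
Formicinae,Myrmecocystus,yuma,dark,38.7,7.1,3,matinal-crepuscular,variable,0.0378,0.0009,287.0,4.2,13.25,0.21,1.12,0.02,0.0825,0.0079,397.1,14.4,14.42,0.50,1.7434
Myrmicinae,Aphaenogaster,boulderensis,dark,53.7,8.0,2,"crepuscular, nocturnal, matinal",variable,0.0480,0.0000,147.5,3.5,19.88,0.38,2.14,0.02,0.0176,0.0067,81.3,18.7,18.49,1.03,1.5468
Myrmicinae,Aphaenogaster,megommata,pale,76.9,2.9,6,"crepuscular, nocturnal",variable,0.0815,0.0032,241.4,7.9,23.10,0.23,1.68,0.03,0.0745,0.0020,226.1,5.7,22.78,0.31,1.5468
Myrmicinae,Aphaenogaster,occidentalis,dark,46.7,3.4,6,variable,variable,0.0264,0.0008,79.8,2.1,19.58,0.26,1.42,0.03,0.0328,0.0019,93.7,5.4,19.87,0.30,1.5468
Myrmicinae,Aphaenogaster,patruelis,dark,42.4,4.2,9,variable,variable,0.0331,0.0019,104.1,4.9,19.96,0.26,1.44,0.02,0.0388,0.0019,116.6,5.3,20.22,0.29,1.5468
Myrmicinae,Temnothorax,BCA-5,pale,87.3,0.2,2,nocturnal,nocturnal,0.0238,0.0026,92.2,6.9,18.30,0.29,0.93,0.06,0.0201,0.0011,80.8,3.7,17.76,0.39,0.7534
Myrmicinae,Temnothorax,neomexicanus,dark,35.4,2.8,4,crepuscular,variable,0.0109,0.0002,66.3,0.9,13.17,0.16,0.67,0.02,0.0128,0.0006,72.0,2.1,14.43,0.23,0.7534
Myrmicinae,Temnothorax,tricarinatus,dark,39.3,3.2,3,crepuscular,variable,0.0138,0.0003,89.0,2.1,13.46,0.23,0.77,0.02,0.0135,0.0005,88.1,1.7,13.42,0.10,0.7534
Myrmicinae,Veromessor,andrei,dark,40.1,2.2,15,variable,variable,0.0663,0.0045,198.4,9.1,21.00,0.29,2.14,0.06,0.0492,0.0022,170.5,4.9,20.27,0.29,1.8333
Myrmicinae,Veromessor,chamberlini,dark,47.9,4.2,6,diurnal,diurnal,0.0395,0.0013,126.7,3.2,19.60,0.23,1.62,0.03,0.0513,0.0021,145.9,4.7,20.11,0.28,1.8333
Myrmicinae,Veromessor,chicoensis,dark,44.6,2.1,6,variable,variable,0.0678,0.0062,167.6,10.1,21.00,0.26,1.92,0.09,0.0629,0.0019,159.6,4.2,20.79,0.25,1.8333
Myrmicinae,Veromessor,julianus,dark,46.1,4.1,6,crepuscular-nocturnal-matinal,variable,0.0771,0.0038,198.8,7.7,22.07,0.27,2.09,0.06,0.0629,0.0020,175.5,4.5,21.46,0.26,1.8333
Myrmicinae,Veromessor,lariversi,pale,68.5,1.6,9,nocturnal,nocturnal,0.0796,0.0027,223.5,4.9,21.00,0.31,1.61,0.05,0.0920,0.0019,243.7,4.4,21.53,0.26,1.8333
Myrmicinae,Veromessor,lobognathus,dark,50.4,5.0,6,variable,variable,0.0808,0.0024,223.8,2.4,20.98,0.33,1.94,0.05,0.0752,0.0020,214.7,4.5,20.74,0.27,1.8333
Myrmicinae,Veromessor,pergandei,dark,32.3,1.8,4,variable,variable,0.0805,0.0049,231.9,8.8,19.87,0.26,1.90,0.06,0.0771,0.0018,226.3,4.0,19.72,0.24,1.8333
Myrmicinae,Veromessor,RAJ-pseu,pale,65.1,1.6,8,nocturnal,nocturnal,0.0910,0.0016,250.6,3.6,21.17,0.26,1.47,0.18,0.1112,0.0022,283.7,4.9,22.04,0.29,1.8333
Myrmicinae,Veromessor,smithi,dark,55.5,3.9,6,crepuscular-nocturnal,variable,0.1010,0.0035,240.1,5.8,22.52,0.32,1.79,0.04,0.1032,0.0020,243.6,4.5,22.61,0.26,1.8333
Myrmicinae,Veromessor,stoddardi,dark,42.9,1.2,4,crepuscular-nocturnal,variable,0.0483,0.0035,130.7,6.4,20.43,0.31,1.85,0.08,0.0476,0.0018,129.5,4.0,20.40,0.24,1.8333
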