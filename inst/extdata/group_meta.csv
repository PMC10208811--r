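group,mya,a_common,b,sleep_h,tb_c,n_species
Fishes,465,0.264,0.88,NA,NA,25000
Amphibia,365,0.366,0.88,NA,NA,4000
Reptilia,322,0.398,0.76,NA,NA,8000
Monotremata,217,1.63,NA,14.0,32.0,4
Marsupialia,193,2.69,0.75,13.0,35.5,346
Eutheria,115,3.53,0.74,10.5,37.0,5136
Palaeognathae,110,3.29,0.73,10.0,38.5,57
Non-Passeriformes,90,4.65,0.69,9.0,39.5,4000
Passeriformes,50,6.18,0.67,7.8,40.5,6000
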