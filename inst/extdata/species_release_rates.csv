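station,species,replicate,t_c_h,t_i_h,r_squared,n_total,rate_pmol_ind_h,rate_umol_gC_h
111,Calanus sp.,A,8,8,0.807,30,17.9,7.6
111,Calanus sp.,B,8,8,0.772,30,6.9,4.4
111,Calanus sp.,C,8,8,0.851,35,16.7,7.0
59,Acartia sp.,A,5,8,0.877,37,7.9,3.4
59,Acartia sp.,B,5,8,0.878,35,7.2,4.6
59,Acartia sp.,C,5,8,0.949,35,7.9,3.2
115,Clausocalanus sp.,A,5,8,0.616,35,5.5,3.8
115,Clausocalanus sp.,B,5,8,0.817,35,4.7,3.3
115,Clausocalanus sp.,C,5,8,0.740,35,7.1,5.1
111,Centropages sp.,A,8,8,0.868,30,3.8,1.1
111,Centropages sp.,B,8,8,0.841,30,4.5,1.8
111,Centropages sp.,C,8,8,0.915,30,3.8,1.1
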