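region,rr_c_nmol_ind_d,abundance_lo_ind_L,abundance_hi_ind_L,ambient_tau_nM
GoA,10.2,3.510,5.088,2.5
NA,0.58,1.897,4.483,2.6
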