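cruise,station,replicate,t_c_h,t_i_h,r_squared,n_total,rate_pmol_ind_h,rate_umol_gC_h,neocalanus_pct,themisto_pct,vibilia_pct,acartia_pct,calanus_pct,centropages_pct
GoA,5,A,24,24,0.970,50,316.8,0.9,32,26,42,,,
GoA,5,B,24,24,0.907,83,480.2,0.5,51,22,28,,,
GoA,8,A,8,24,0.984,38,570.8,1.7,0,63,37,,,
GoA,12,A,8,24,0.955,51,331.8,0.5,59,35,6,,,
GoA,17,A,10,24,0.977,53,356.0,0.7,79,19,2,,,
GoA,20,A,8,24,0.998,54,498.3,0.6,78,19,4,,,
GoA,29,A,8,24,0.856,39,421.8,0.6,56,18,26,,,
NA,14,A,3,24,0.814,44,24.7,8.9,,,,14,45,41
NA,14,B,3,24,0.851,41,24.5,7.7,,,,20,32,49
NA,14,C,3,24,0.970,49,24.1,11.8,,,,20,20,59
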