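material,n_labs,X_obs_nm,S_r_nm,r_nm,RSD_r_pct,S_R_nm,R_nm,RSD_R_pct
ERM-FD100,17,17.4,0.3,0.8,1.8,0.3,0.9,1.8
Gold nanorods,19,15.93,0.7,2.0,4.6,0.8,2.2,5.2
NM-100,18,97.4,4.7,13.2,4.8,5.7,15.9,5.8
NM-212,18,13.7,1.0,2.9,7.5,1.8,5.2,13.6
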