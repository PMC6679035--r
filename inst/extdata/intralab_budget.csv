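material,magnification,partner,C_m_nm,sd_nm,u_r_pct,u_day_pct,u_IP_pct,u_cal_pct,u_t_pct,u_c_pct,Ucx_pct
ERM-FD100,18500,P1,17.4,0.3,1.5,1.0,1.8,1.0,3.8,4.3,8.6
ERM-FD100,18500,P2,17.5,0.3,1.5,1.1,1.9,1.0,4.1,4.7,9.5
ERM-FD100,18500,P3,17.3,0.3,1.7,0.6,1.7,1.0,3.7,4.3,8.6
ERM-FD100,68000,P1,18.1,0.3,1.5,1.2,1.9,0.2,3.9,4.3,8.6
ERM-FD100,68000,P2,18.4,0.4,2.0,1.0,2.3,0.2,4.1,4.6,9.3
ERM-FD100,68000,P3,17.3,0.4,1.5,1.8,2.4,0.2,4.1,4.7,9.5
ERM-FD304,18500,P1,22.9,0.3,1.2,0.5,1.3,1.0,3.0,3.4,6.8
ERM-FD304,18500,P2,23.3,0.7,1.2,2.8,3.0,1.0,4.0,5.1,10.3
ERM-FD304,18500,P3,22.8,0.3,1.3,0.5,1.4,1.0,3.0,3.5,7.0
ERM-FD304,68000,P1,23.0,0.3,1.5,0.4,1.5,0.2,3.1,3.5,6.9
ERM-FD304,68000,P2,23.5,0.5,1.2,1.9,2.2,0.2,3.5,4.1,8.3
ERM-FD304,68000,P3,23.0,0.4,1.7,0.7,1.8,0.2,3.3,3.8,7.5
Gold nanorods,18500,P1,15.8,0.5,3.1,1.2,3.4,1.0,4.5,5.7,11.4
Gold nanorods,18500,P2,15.1,1.0,6.9,2.7,7.4,1.0,8.0,10.9,21.9
Gold nanorods,18500,P3,15.2,0.7,4.0,1.7,4.4,1.0,5.3,6.9,13.9
NM-100,9300,P1,100,2,1.9,0.7,2.1,0.8,3.6,4.3,8.5
NM-100,9300,P2,103,3,2.6,0.5,2.6,0.8,4.0,4.8,9.7
NM-100,9300,P3,105,2,2.2,0.7,2.3,0.8,3.8,4.5,9.0
NM-103,30000,P1,18.2,0.4,2.1,1.3,2.5,0.1,3.9,4.6,9.2
NM-103,30000,P2,21.4,0.7,2.6,1.8,3.1,0.1,4.3,5.3,10.7
NM-103,30000,P3,21.3,0.4,2.0,0.8,2.1,0.1,3.7,4.3,8.5
NM-212,30000,P1,15.6,1.0,6.4,2.0,6.7,0.1,7.3,9.9,19.9
NM-212,30000,P2,15.6,1.4,8.5,3.0,9.0,0.1,9.5,13.1,26.2
NM-212,30000,P3,17.6,1.1,6.3,0.8,6.3,0.1,7.0,9.4,18.9
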