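material,magnification,C_m_nm,u_c_nm,C_crm_nm,u_crm_nm,delta_m_nm,u_delta_nm,U_delta_nm
ERM-FD100,18500,19.2,0.9,19.4,0.7,0.2,1.1,2.3
ERM-FD100,68000,19.4,0.8,19.4,0.7,0.0,1.1,2.1
ERM-FD304,18500,25.5,1.3,27.8,0.8,2.3,1.5,3.1
ERM-FD304,68000,24.9,1.0,27.8,0.8,2.9,1.3,2.6
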