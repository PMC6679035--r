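material,magnification,fov_nm,n_pixels,mode,lod_nm,lloq_nm,uloq_nm
ERM-FD100,18500,2450,4096,default,0.60,6.0,245.0
ERM-FD100,68000,660,4096,default,0.16,1.6,66.0
ERM-FD304,18500,2450,4096,default,0.60,6.0,245.0
ERM-FD304,68000,660,4096,default,0.16,1.6,66.0
Gold nanorods,18500,2450,4096,irregular_watershed,0.60,6.0,245.0
NM-100,9300,4777,4096,ellipse_fitting,1.17,11.7,477.7
NM-103,30000,1537,4096,single_particle,0.38,3.8,153.7
NM-212,30000,1537,4096,single_particle,0.38,3.8,153.7
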