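id,comparison,group,n,bias,bias_ci_low,bias_ci_high,loa_lower,loa_lower_ci_low,loa_lower_ci_high,loa_upper,loa_upper_ci_low,loa_upper_ci_high,cr
t1,Obs 1 vs Obs 1 (intra),retinal_volume,30,0.0074,0.0048,0.0100,-0.0067,-0.0144,0.0010,0.0215,0.0138,0.0292,0.0141
t2,Obs 2 vs Obs 2 (intra),retinal_volume,30,0.0066,0.0042,0.0090,-0.0066,-0.0139,0.0006,0.0198,0.0125,0.0270,0.0132
t3,Obs 1 - Obs 2,retinal_volume,30,-0.0021,-0.0041,-0.0001,-0.0132,-0.0193,-0.0071,0.0090,0.0029,0.0151,0.0111
t4,Automated - Obs 1,retinal_volume,30,-0.0041,-0.0067,-0.0015,-0.0184,-0.0262,-0.0106,0.0102,0.0024,0.0180,0.0143
t5,Automated - Obs 2,retinal_volume,30,-0.0062,-0.0088,-0.0036,-0.0203,-0.0280,-0.0126,0.0079,0.0002,0.0156,0.0141
t6,Obs 1 vs Obs 1 (intra),foveal_cavity,32,-0.0021,-0.0061,0.0020,-0.0242,-0.0359,-0.0125,0.0201,0.0083,0.0318,0.0221
t7,Obs 2 vs Obs 2 (intra),foveal_cavity,32,-0.0048,-0.0080,-0.0016,-0.0222,-0.0315,-0.0130,0.0126,0.0034,0.0219,0.0174
t8,Obs 1 - Obs 2,foveal_cavity,32,-0.0004,-0.0020,0.0011,-0.0088,-0.0132,-0.0043,0.0079,0.0035,0.0123,0.0083
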