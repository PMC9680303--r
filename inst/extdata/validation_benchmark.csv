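compound,ebrt_s,inlet_g_m3,outlet_exp_g_m3,outlet_refmodel_g_m3,error_refmodel_pct,outlet_reported_g_m3,error_reported_pct
benzene,60,0.13,0.11,0.11,0,0.10,-9.1
benzene,78,0.21,0.16,0.16,0,0.16,0
benzene,84,0.17,0.13,0.13,0,0.13,0
benzene,90,0.19,0.15,0.14,-6.2,0.14,-6.2
benzene,120,0.15,0.12,0.10,-16.7,0.10,-16.7
benzene,186,0.37,0.19,0.19,0,0.19,0
toluene,60,0.21,0.17,0.16,-5.9,0.16,-5.9
toluene,78,0.4,0.27,0.28,3.7,0.27,0
toluene,84,0.38,0.24,0.26,8.3,0.25,4.2
toluene,90,0.27,0.19,0.18,-5.3,0.18,-5.3
toluene,120,0.3,0.16,0.17,6.2,0.17,6.2
toluene,186,0.23,0.1,0.09,-10,0.09,-10
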