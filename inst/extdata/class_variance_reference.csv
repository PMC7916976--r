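lipid_class,z,p_z,icc,f_time,p_time,f_order,p_order
GM3,1.43,0.076,0.35,5.21,0.035,1.90,0.19
Cer,2.27,0.012,0.61,1.66,0.214,1.46,0.24
Hex1Cer,2.45,0.007,0.68,3.85,0.065,0.78,0.39
Hex2Cer,1.83,0.034,0.46,3.78,0.068,0.00,0.99
LPC,2.49,0.006,0.70,1.17,0.293,0.33,0.57
LPE,2.54,0.006,0.72,3.26,0.088,0.66,0.43
PE,2.10,0.018,0.55,13.72,0.002,1.48,0.24
PI,2.13,0.017,0.56,5.81,0.027,1.25,0.28
PC,2.04,0.020,0.53,4.15,0.057,1.62,0.22
PS,1.92,0.027,0.49,3.84,0.066,0.85,0.37
SM,1.90,0.029,0.49,2.35,0.143,0.56,0.47
DAG,2.59,0.005,0.74,1.30,0.270,1.45,0.24
TAG,1.89,0.029,0.48,7.95,0.011,1.18,0.29
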