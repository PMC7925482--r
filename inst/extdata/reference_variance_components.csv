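trait,sigma2_G,sigma2_GE,sigma2_e,n_env,n_rep,h2_published
nStr_8WAP,10.13,13.72,31.24,3,2,0.51
nStr_10WAP,163.41,159.44,460.87,3,2,0.56
nStr_12WAP,579.53,313.28,990.88,3,2,0.68
AUSNPC,1460.78,1208.30,2270.43,3,2,0.65
SDR,0.78,0.10,0.72,3,2,0.84
GY,0.28,0.11,0.53,3,2,0.70
AD,15.26,1.45,4.93,3,2,0.92
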