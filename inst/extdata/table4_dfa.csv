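food_type,axis1_corr,wilks_without,f_remove,p
Detritus,-0.64,0.51,5.45,0.023
Benthic,0.05,0.47,0.48,0.490
Epiphytic,0.39,0.46,0.12,0.733
Epiphytic_Benthic,-0.65,0.62,18.36,0.000
Planktonic,0.41,0.462,0.00,0.943
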