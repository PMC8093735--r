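index,juv_avg,juv_se,mat_avg,mat_se,perm_p
D,0.17,0.04,0.11,0.03,0.016
B,4.91,0.36,5.33,0.45,0.407
H,2.38,0.24,2.52,0.14,0.383
Ba,0.35,0.02,0.36,0.03,0.928
J,0.64,0.01,0.69,0.03,0.340
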