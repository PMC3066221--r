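dhm,mortality_fraction,source_label
0.3,0.006,MHI72
0.8,0.012,MHI72
1.5,0.049,MHI72
2.2,0.07,MHI72
3.1,0.105,MHI72
4,0.174,MHI72
5.2,0.212,MHI72
6.5,0.33,MHI72
8,0.45,MHI72
9.6,0.665,MHI72
0.5,0,NWHI02
1.8,0.032,NWHI02
2.9,0.101,NWHI02
4.4,0.162,NWHI02
6.1,0.267,NWHI02
7.4,0.412,NWHI02
0.4,0.005,Carib05
1.1,0.112,Carib05
2,0.125,Carib05
2.8,0.224,Carib05
3.6,0.367,Carib05
4.5,0.513,Carib05
5.3,0.716,Carib05
6.2,0.958,Carib05
7,1,Carib05
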