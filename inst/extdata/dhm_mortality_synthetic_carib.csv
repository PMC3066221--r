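dhm,mortality_fraction,source_label
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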