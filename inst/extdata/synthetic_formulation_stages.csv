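stage,cutoff_um,mass_ug
1,8.06,2.1311
2,4.46,6.5012
3,2.82,6.9617
4,1.66,5.4206
5,0.94,1.7589
6,0.55,0.2135
7,0.34,0.0130
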