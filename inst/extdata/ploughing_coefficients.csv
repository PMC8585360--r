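theta_deg,replicate,fp
0,1,0.29
0,2,0.29
0,3,0.29
0,4,0.30
0,5,0.30
45,1,1.23
45,2,1.21
45,3,1.21
45,4,1.22
45,5,1.22
90,1,0.55
90,2,0.55
90,3,0.55
90,4,0.58
90,5,0.58
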