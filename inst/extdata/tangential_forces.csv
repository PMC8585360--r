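h_mm,theta_deg,replicate,fp_n
0.5,0,1,64.35
0.5,0,2,80.04
0.5,0,3,60.56
0.5,0,4,71.70
0.5,0,5,75.46
0.6,0,1,88.61
0.6,0,2,95.58
0.6,0,3,92.24
0.6,0,4,96.63
0.6,0,5,78.30
0.8,0,1,126.84
0.8,0,2,146.06
0.8,0,3,142.96
0.8,0,4,141.90
0.8,0,5,171.60
0.5,45,1,314.57
0.5,45,2,277.75
0.5,45,3,266.73
0.5,45,4,296.38
0.5,45,5,255.31
0.6,45,1,374.95
0.6,45,2,383.11
0.6,45,3,393.60
0.6,45,4,349.87
0.6,45,5,395.99
0.8,45,1,528.01
0.8,45,2,528.79
0.8,45,3,542.52
0.8,45,4,534.53
0.8,45,5,525.84
0.5,90,1,145.83
0.5,90,2,136.02
0.5,90,3,164.39
0.5,90,4,155.29
0.5,90,5,128.36
0.6,90,1,172.33
0.6,90,2,194.27
0.6,90,3,188.69
0.6,90,4,190.56
0.6,90,5,160.52
0.8,90,1,282.28
0.8,90,2,299.33
0.8,90,3,266.69
0.8,90,4,244.23
0.8,90,5,312.95
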