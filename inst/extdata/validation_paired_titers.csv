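group,label,reference_titer,evaluated_titer
A,1,1.00e9,1.07e9
A,2,7.33e8,8.67e8
A,3,1.53e9,1.40e9
A,4,8.67e8,1.00e9
B,1,1.00e8,1.33e8
B,2,1.20e8,1.20e8
B,3,1.07e8,1.47e8
B,4,1.47e8,1.20e8
C,1,7.33e6,1.33e7
C,2,1.40e7,1.07e7
C,3,1.07e7,1.27e7
C,4,1.00e7,1.33e7
D,1,1.53e6,1.13e6
D,2,1.73e6,1.13e6
D,3,2.07e6,1.00e6
D,4,1.27e6,8.67e5
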