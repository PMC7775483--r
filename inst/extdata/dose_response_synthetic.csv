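"ros_um","activity_norm"
0,0.3755
10,0.5445
25,0.6547
45,0.8005
70,0.8358
110,0.8604
200,0.9492
400,0.9957
1000,1
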