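dataset,keyframe,mae_mm
8,0,9.25
8,1,2.91
8,2,2.21
8,3,2.15
8,4,2.43
9,0,6.05
9,1,1.72
9,2,6.79
9,3,2.27
9,4,1.24
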