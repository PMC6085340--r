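optode,x_mm,y_mm,z_mm
1,0,-0,0
2,15,-0,0
3,30,-0,0
4,45,-0,0
5,60,-0,0
6,75,-0,0
7,90,-0,0
8,105,-0,0
9,7.5,-12.990381056766578,0
10,22.5,-12.990381056766578,0
11,37.5,-12.990381056766578,0
12,52.5,-12.990381056766578,0
13,67.5,-12.990381056766578,0
14,82.5,-12.990381056766578,0
15,97.5,-12.990381056766578,0
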