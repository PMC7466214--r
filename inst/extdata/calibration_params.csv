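name,slope,intercept,r_squared,range_low,range_high
BHT,1.3579,-0.0011,0.9999,0.0025,2
DEP,1.8091,-0.0249,0.9994,0.01,2
DIBP,2.5364,-0.0151,0.9990,0.005,2
DBP,2.6487,-0.0284,0.9990,0.0025,2
ATBC,0.1684,-0.0108,0.9930,0.025,2
DEHP,1.0437,-0.0158,0.9960,0.025,2
Octocrylene,0.1509,-0.0037,0.9970,0.01,2
DNOP,1.5027,-0.0615,0.9970,0.025,2
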