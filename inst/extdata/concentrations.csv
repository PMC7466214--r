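analyte,age_group,corrected,censor_status,recovery_percent
DEP,1-2,0.329,quantified,98
DEP,3-9,0.279,quantified,96
DEP,10-17,0.205,quantified,92
DIBP,1-2,0.0516,quantified,90
DIBP,3-9,0.0344,quantified,102
DIBP,10-17,0.102,quantified,82
DBP,1-2,0.0370,quantified,100
DBP,3-9,0.0250,quantified,103
DBP,10-17,0.0426,quantified,98
ATBC,1-2,0.0393,quantified,118
ATBC,3-9,0.0554,quantified,114
ATBC,10-17,0.0527,quantified,113
BHT,1-2,0.0148,quantified,73
BHT,3-9,0.0476,quantified,75
BHT,10-17,0.00762,quantified,74
Octocrylene,1-2,0.0257,quantified,83
Octocrylene,3-9,0.0164,quantified,80
Octocrylene,10-17,0.0319,quantified,79
DEHP,1-2,0.0949,quantified,72
DEHP,3-9,0.101,quantified,90
DEHP,10-17,0.524,quantified,93
DNOP,1-2,,below_loq,84
DNOP,3-9,,below_loq,85
DNOP,10-17,,below_loq,74
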