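name,cas,quant_ion,qual_ion,lod_extract,loq_extract,tdi,sml,cramer_class,group_tdi_member,potency_factor
BHT,128-37-0,205,220,0.001,0.0025,,3,II,FALSE,1
DEP,84-66-2,149,177,0.005,0.01,500,,I,FALSE,1
DIBP,84-69-5,149,150,0.0025,0.005,,,I,FALSE,1
DBP,84-74-2,149,150,0.001,0.0025,10,0.3,I,TRUE,1
ATBC,77-90-7,185,129,0.01,0.025,,60,I,FALSE,1
DEHP,117-81-7,149,167,0.01,0.025,50,1.5,I,TRUE,1
Octocrylene,6197-30-4,204,232,0.005,0.01,,0.05,III,FALSE,1
DNOP,117-84-0,149,279,0.01,0.025,,,I,FALSE,1
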