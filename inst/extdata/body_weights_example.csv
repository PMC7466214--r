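age_group,body_weight
1-2,12
3-9,24
10-17,50
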