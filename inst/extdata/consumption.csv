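age_group,intake_mean,intake_p95,mode,body_weight
1-2,1.671,8.508,per_kg_bw,
3-9,0.9806,4.265,per_kg_bw,
10-17,0.3705,1.932,per_kg_bw,
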