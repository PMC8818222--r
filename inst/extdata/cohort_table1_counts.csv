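character,count,printed_pct
male,9,43
female,12,57
current_smoker,1,5
former_smoker,5,24
never_smoker,15,71
egfr_mut,17,81
alk_rearrangement,3,14
kras_mut,1,5
lmc,5,24
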