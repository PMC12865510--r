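fragment_id,area_ha,survey_design
f1,1,effort_controlled
f2,5,effort_controlled
f3,12,effort_controlled
f4,40,effort_controlled
f5,150,effort_controlled
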