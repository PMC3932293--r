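fracture_type,admissions,total_cost_eur
hip_femur,4653,14077146.05
vertebral,2318,2549459.76
other,3254,6297477.79
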