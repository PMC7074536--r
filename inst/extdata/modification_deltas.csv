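name,formula_change,delta_mass
hydroxylation,+O,15.9949146
methylation,+CH2,14.0156500
dehydrogenation,-H2,-2.0156500
reduction,+H2,2.0156500
methoxylation-dehydrogenation,+CO,27.9949146
bromination,+Br-H,77.9105121
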