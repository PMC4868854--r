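88bd866d552bb6cc0908170449a46617  table1_effect_sizes.csv
df3fa399e2982b5b9e15bde40407bc47  table2_cluster_composition.csv
e3a36f13970c0b0157c36cf02459320a  drivers_synthetic.csv
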