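key,value,units,source,version
TIP3P,100,dimensionless,"static dielectric constant of the TIP3P water model (simulation estimate, +/- 5)",2024
TIP4P-Ew,64,dimensionless,"static dielectric constant of the TIP4P-Ew water model (simulation estimate, +/- 1)",2024
experiment,78.4,dimensionless,"static dielectric constant of water at 298 K (experiment)",2024
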