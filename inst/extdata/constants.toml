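# Energetic constants (see ?energetic_constants for units and meaning)
[constants]
gas_constant = 1.9872
Ts = 385.15
dS_rt = -8
alpha = 0.45
beta = -0.26
f_ap = 0.68
asa_per_residue = 47
dS_per_rotor = 1.7
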