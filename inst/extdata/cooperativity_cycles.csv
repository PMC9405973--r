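# Heterotropic cooperativity cycle specification: each effect is the
# ratio of the numerator to the denominator association constant.
effect_label,numerator_complex,denominator_complex
Mg-on-GTP (Sdo1-bound),R1086Q-Sdo1.GTP.Mg,R1086Q-Sdo1.GTP
Mg-on-GDP (Sdo1-bound),R1086Q-Sdo1.GDP.Mg,R1086Q-Sdo1.GDP
Mg-on-GTP (free),R1086Q.GTP.Mg,R1086Q.GTP
Mg-on-GDP (free),R1086Q.GDP.Mg,R1086Q.GDP
Sdo1-on-MgGTP,R1086Q-Sdo1.GTP.Mg,R1086Q.GTP.Mg
Sdo1-on-MgGDP,R1086Q-Sdo1.GDP.Mg,R1086Q.GDP.Mg
Sdo1-on-GTP,R1086Q-Sdo1.GTP,R1086Q.GTP
Sdo1-on-GDP,R1086Q-Sdo1.GDP,R1086Q.GDP
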