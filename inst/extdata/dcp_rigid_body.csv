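# Rigid-body heat-capacity change per nucleotide complex, cal/mol/K,
# computed from buried polar/apolar surface areas of the modelled
# complexes (taken as inputs; no structure calculation is performed
# here). Keyed by ligand and magnesium state.
ligand,mg_state,dCp_rb_cal
GTP,+Mg,-25
GTP,-Mg,-11
GDP,+Mg,-48
GDP,-Mg,-30
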