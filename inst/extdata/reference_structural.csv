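# Reference transcription of the published structural-energetic
# deconvolution at 30 degC for the Efl1 R1086Q series. All cells are
# printed as integers. dCp_err_cal repeats the printed standard error of
# the heat-capacity fit (used to propagate tolerance into the cells that
# depend on the fitted dCp).
complex_label,dCp_conf_cal,minus_dASA_conf,n_conf_residues,dS_cal,dS_solv_cal,dS_conf_cal,n_rot_bonds,dCp_err_cal
R1086Q.GTP.Mg,35,-157,3,25,-2,36,21,2
R1086Q.GTP,41,-184,4,29,-7,44,27,6
R1086Q.GDP.Mg,-222,996,21,7,65,-49,30,40
R1086Q.GDP,-220,987,21,-1,60,-53,31,17
R1086Q-Sdo1.GTP.Mg,-375,1683,36,9,96,-78,47,11
R1086Q-Sdo1.GTP,41,-184,4,9,-7,24,14,6
R1086Q-Sdo1.GDP.Mg,-267,1198,25,11,75,-57,34,9
R1086Q-Sdo1.GDP,-520,2334,50,3,132,-121,72,18
R1086Q_P151L.GTP.Mg,-195,875,19,13,53,-31,19,35
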