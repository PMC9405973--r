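# Reference transcription of the published derived state-function cells
# (dissociation constant, binding free energy, entropic term, van't Hoff
# heat capacity) for the Efl1 R1086Q series. *_dp columns record the
# number of printed decimal places of each cell; dCp_err_cal is the
# printed standard error of the heat-capacity fit (reported once per
# complex, carried on the 30 degC row).
complex_label,temperature_C,Kd_uM,Kd_dp,dG_kcal,dG_dp,minus_TdS_kcal,mTdS_dp,dCp_cal,dCp_err_cal
R1086Q.GTP.Mg,25,16,0,-6.53,2,-7.57,2,NA,NA
R1086Q.GTP.Mg,30,16,0,-6.67,2,-7.74,2,10,2
R1086Q.GTP.Mg,35,13,0,-6.88,2,-8.0,1,NA,NA
R1086Q.GTP,25,17,0,-6.52,2,-8.12,2,NA,NA
R1086Q.GTP,30,6,0,-7.20,2,-8.90,2,30,6
R1086Q.GTP,35,6,0,-7.40,2,-9.30,2,NA,NA
R1086Q.GDP.Mg,25,24,0,-6.29,2,-3.19,2,NA,NA
R1086Q.GDP.Mg,30,28,0,-6.30,2,-2.20,2,-270,40
R1086Q.GDP.Mg,35,29,0,-6.39,2,-0.59,2,NA,NA
R1086Q.GDP,25,3,0,-7.54,2,-0.94,2,NA,NA
R1086Q.GDP,30,4,0,-7.47,2,0.22,2,-250,17
R1086Q.GDP,35,4,0,-7.55,2,1.55,2,NA,NA
R1086Q_P151L.GTP.Mg,25,18,0,-6.5,1,-4.8,1,NA,NA
R1086Q_P151L.GTP.Mg,30,17,0,-6.6,1,-4.1,1,-220,35
R1086Q_P151L.GTP.Mg,35,18,0,-6.7,1,-2.8,1,NA,NA
R1086Q.Sdo1,25,3.9,1,-7.4,1,-3.1,1,NA,NA
R1086Q.Sdo1,30,3.4,1,-7.6,1,-1.3,1,-440,23
R1086Q.Sdo1,35,1.8,1,-8.1,1,0.6,1,NA,NA
R1086Q-Sdo1.GTP.Mg,25,29,0,-6.2,1,-5.1,1,NA,NA
R1086Q-Sdo1.GTP.Mg,30,58,0,-5.9,1,-2.9,1,-400,11
R1086Q-Sdo1.GTP.Mg,35,52,0,-6.0,1,-0.9,1,NA,NA
R1086Q-Sdo1.GTP,25,17,0,-6.5,1,-2.5,1,NA,NA
R1086Q-Sdo1.GTP,30,23,0,-6.5,1,-2.6,1,30,6
R1086Q-Sdo1.GTP,35,25,0,-6.5,1,-2.8,1,NA,NA
R1086Q-Sdo1.GDP.Mg,25,9,0,-6.9,1,-4.7,1,NA,NA
R1086Q-Sdo1.GDP.Mg,30,8,0,-7.1,1,-3.3,1,-315,9
R1086Q-Sdo1.GDP.Mg,35,6,0,-7.3,1,-2.0,1,NA,NA
R1086Q-Sdo1.GDP,25,17,0,-6.5,1,-4.0,1,NA,NA
R1086Q-Sdo1.GDP,30,30,0,-6.3,1,-1.0,1,-550,18
R1086Q-Sdo1.GDP,35,34,0,-6.30,2,1.7,1,NA,NA
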