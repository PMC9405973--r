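# Measured ITC binding parameters (association constant and enthalpy per
# complex per temperature) for the Efl1 R1086Q calorimetric study:
# guanine nucleotides binding the free GTPase, the GTPase-Sdo1 complex,
# the Sdo1 interaction itself, and the R1086Q P151L double mutant.
# Wild-type values measured at 30 degC only are carried as a separate
# series (source = wildtype) for delta-vs-wild-type comparisons.
# Units: temperature_C degC, Kb mM^-1, dH kcal/mol. n was not reported
# and is set to 1.
complex_label,ligand,mg_state,temperature_C,n,Kb_mM,Kb_err_mM,dH_kcal,dH_err_kcal,source
R1086Q.GTP.Mg,GTP,+Mg,25,1,61,7,1.04,0.05,R1086Q
R1086Q.GTP.Mg,GTP,+Mg,30,1,64,11,1.07,0.03,R1086Q
R1086Q.GTP.Mg,GTP,+Mg,35,1,76,10,1.12,0.06,R1086Q
R1086Q.GTP,GTP,-Mg,25,1,60,18,1.6,0.3,R1086Q
R1086Q.GTP,GTP,-Mg,30,1,156,34,1.7,0.1,R1086Q
R1086Q.GTP,GTP,-Mg,35,1,178,28,1.9,0.1,R1086Q
R1086Q.GDP.Mg,GDP,+Mg,25,1,41,5,-3.1,0.1,R1086Q
R1086Q.GDP.Mg,GDP,+Mg,30,1,35,7,-4.1,0.6,R1086Q
R1086Q.GDP.Mg,GDP,+Mg,35,1,34,9,-5.8,0.2,R1086Q
R1086Q.GDP,GDP,-Mg,25,1,336,47,-6.6,0.2,R1086Q
R1086Q.GDP,GDP,-Mg,30,1,245,37,-7.7,0.3,R1086Q
R1086Q.GDP,GDP,-Mg,35,1,226,34,-9.1,0.3,R1086Q
R1086Q_P151L.GTP.Mg,GTP,+Mg,25,1,55,10,-1.7,0.1,R1086Q_P151L
R1086Q_P151L.GTP.Mg,GTP,+Mg,30,1,59,8,-2.5,0.1,R1086Q_P151L
R1086Q_P151L.GTP.Mg,GTP,+Mg,35,1,54,5,-3.9,0.1,R1086Q_P151L
R1086Q.Sdo1,Sdo1,na,25,1,256,47,-4.3,0.1,R1086Q
R1086Q.Sdo1,Sdo1,na,30,1,288,56,-6.3,0.2,R1086Q
R1086Q.Sdo1,Sdo1,na,35,1,543,76,-8.7,0.1,R1086Q
R1086Q-Sdo1.GTP.Mg,GTP,+Mg,25,1,34,3,-1.1,0.04,R1086Q
R1086Q-Sdo1.GTP.Mg,GTP,+Mg,30,1,17,1,-3.0,0.2,R1086Q
R1086Q-Sdo1.GTP.Mg,GTP,+Mg,35,1,19,2,-5.1,0.4,R1086Q
R1086Q-Sdo1.GTP,GTP,-Mg,25,1,57,6,-4.0,0.2,R1086Q
R1086Q-Sdo1.GTP,GTP,-Mg,30,1,44,1,-3.9,0.1,R1086Q
R1086Q-Sdo1.GTP,GTP,-Mg,35,1,39,8,-3.7,0.4,R1086Q
R1086Q-Sdo1.GDP.Mg,GDP,+Mg,25,1,110,23,-2.1,0.08,R1086Q
R1086Q-Sdo1.GDP.Mg,GDP,+Mg,30,1,125,14,-3.8,0.05,R1086Q
R1086Q-Sdo1.GDP.Mg,GDP,+Mg,35,1,158,18,-5.3,0.11,R1086Q
R1086Q-Sdo1.GDP,GDP,-Mg,25,1,57,1.5,-2.5,0.4,R1086Q
R1086Q-Sdo1.GDP,GDP,-Mg,30,1,33,5.0,-5.4,0.6,R1086Q
R1086Q-Sdo1.GDP,GDP,-Mg,35,1,29,4.2,-8.0,0.8,R1086Q
WT.GTP.Mg,GTP,+Mg,30,1,8,0.7,-6.4,0.4,wildtype
WT.GTP,GTP,-Mg,30,1,4,0.3,-7.3,0.3,wildtype
WT.GDP.Mg,GDP,+Mg,30,1,27,3,-5.6,0.2,wildtype
WT.GDP,GDP,-Mg,30,1,64,9,-6.7,0.3,wildtype
WT.Sdo1,Sdo1,na,30,1,3110,630,-13.4,0.4,wildtype
WT-Sdo1.GTP,GTP,-Mg,30,1,89,12,-2.1,0.2,wildtype
WT-Sdo1.GDP,GDP,-Mg,30,1,19,1,-7.4,0.0,wildtype
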