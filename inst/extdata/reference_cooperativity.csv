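# Reference transcription of the published heterotropic cooperativity
# cells for Efl1 R1086Q. *_dp columns give printed decimal places.
effect_label,temperature_C,kappa,kappa_dp,dg_kcal,dg_dp,dh_kcal,dh_dp,minus_Tds_kcal,mTds_dp
Mg-on-GTP (Sdo1-bound),25,0.6,1,0.3,1,2.9,1,-2.6,1
Mg-on-GTP (Sdo1-bound),30,0.3,1,0.6,1,0.9,1,-0.3,1
Mg-on-GTP (Sdo1-bound),35,0.5,1,0.5,1,-1.4,1,1.9,1
Mg-on-GDP (Sdo1-bound),25,1.9,1,-0.4,1,0.3,1,-0.7,1
Mg-on-GDP (Sdo1-bound),30,3.7,1,-0.8,1,1.6,1,-2.4,1
Mg-on-GDP (Sdo1-bound),35,5.4,1,-1.0,1,2.7,1,-3.7,1
Mg-on-GTP (free),25,1.0,1,-0.1,1,-0.56,2,0.5,1
Mg-on-GTP (free),30,0.4,1,0.6,1,-0.63,2,1.2,1
Mg-on-GTP (free),35,0.4,1,0.5,1,-0.78,2,1.3,1
Mg-on-GDP (free),25,0.1,1,1.3,1,3.5,1,-2.3,1
Mg-on-GDP (free),30,0.1,1,1.2,1,3.6,1,-2.4,1
Mg-on-GDP (free),35,0.2,1,1.2,1,3.3,1,-2.1,1
Sdo1-on-MgGTP,25,0.6,1,0.3,1,-2.1,1,2.5,1
Sdo1-on-MgGTP,30,0.3,1,0.7,1,-4.1,1,4.8,1
Sdo1-on-MgGTP,35,0.3,1,0.9,1,-6.2,1,7.1,1
Sdo1-on-MgGDP,25,2.7,1,-0.6,1,1.0,1,-1.6,1
Sdo1-on-MgGDP,30,3.6,1,-0.8,1,0.3,1,-1.1,1
Sdo1-on-MgGDP,35,4.6,1,-0.9,1,0.5,1,-1.4,1
Sdo1-on-GTP,25,1.0,1,0.0,1,-5.6,1,5.6,1
Sdo1-on-GTP,30,0.3,1,0.7,1,-5.6,1,6.3,1
Sdo1-on-GTP,35,0.2,1,0.9,1,-5.6,1,6.5,1
Sdo1-on-GDP,25,0.2,1,1.06,2,4.2,1,-3.1,1
Sdo1-on-GDP,30,0.1,1,1.2,1,2.3,1,-1.2,1
Sdo1-on-GDP,35,0.1,1,1.3,1,1.2,1,0.5,1
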