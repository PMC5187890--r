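quantity,strain,pH,condition,value,sd,units
Pf,control,7.4,basal,4.1e-4,5e-5,cm/s
Pf,AQP5,7.4,basal,4.94e-3,4.0e-4,cm/s
Pf,control,5.1,basal,3.5e-4,1e-5,cm/s
Pf,AQP5,5.1,basal,4.77e-3,3.2e-4,cm/s
Pf,AQP5,7.4,glucose,1.060e-2,5.3e-4,cm/s
Pf,AQP5,7.4,glucose_HgCl2,6.26e-3,1.23e-3,cm/s
Ea,control,7.4,basal,15.16,0.85,kcal/mol
Ea,AQP5,7.4,basal,6.52,0.82,kcal/mol
Ea,control,5.1,basal,14.38,0.22,kcal/mol
Ea,AQP5,5.1,basal,7.69,0.86,kcal/mol
k_o2_electrode,control,NA,basal,1.68e-3,1.2e-4,1/s
k_o2_electrode,AQP5,NA,basal,2.39e-3,1.5e-4,1/s
k_h2o2_electrode,control,NA,basal,1.44e-3,4.9e-4,1/s
k_h2o2_electrode,AQP5,NA,basal,4.13e-3,2.6e-4,1/s
catalase,control,NA,basal,0.235,0.012,U/mg
catalase,AQP5,NA,basal,0.163,0.008,U/mg
gsh,control,NA,basal,1.94,0.18,uM/mg
gsh,AQP5,NA,basal,1.53,0.20,uM/mg
membrane_expression,AQP5,5.1,basal,0.37,0.07,relative
membrane_expression,AQP5,7.4,basal,0.35,0.07,relative
membrane_expression,AQP5,5.1,glucose_5min,0.49,0.08,relative
membrane_expression,AQP5,5.1,glucose_15min,0.47,0.12,relative
membrane_expression,AQP5,7.4,glucose_5min,0.37,0.07,relative
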