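parameter,unit,description,typical,bsv_cv,boot_median,boot_lo,boot_hi
cl,L/h/m2,Clearance,87.8,21.4,88.3,72.2,108
vc,L/m2,Volume of central compartment,18.5,,18.2,14.2,23.5
vp,L/m2,Volume of peripheral compartment,22.9,,21.9,15.7,46.1
q,L/h/m2,Intercompartmental clearance,13.1,,13.3,10.0,19.6
ktr_pc,1/h,Rate constant of inter-compartmental platelet movement,0.0244,,0.0246,0.0236,0.0254
slope_pc,mL/ng,Drug effect on platelet count,0.0656,25.7,0.0676,0.0539,0.0930
base_pc,/mm3,Baseline platelet count,49200,105,53700,36100,95800
gamma_pc,-,Shape factor for platelet count fluctuation,0.304,,0.299,0.264,0.325
imp,/mm3,Maximum degree of platelet count recovery expected,55000,78.3,58700,24200,98300
imk,1/h,Rate constant for asymptotic platelet count recovery,0.000530,,0.000513,0.000213,0.000691
ktr_anc,1/h,Rate constant of inter-compartmental neutrophil movement,0.0132,,0.0133,0.0120,0.0139
slope_anc,mL/ng,Drug effect on neutrophil count,0.263,57.5,0.237,0.114,0.363
base_anc,/mm3,Baseline neutrophil count,3240,43.5,3015,2110,4140
gamma_anc,-,Shape factor for neutrophil count fluctuation,0.193,39.4,0.181,0.110,0.251
sigma2_pk_prop,-,Variance of residual error (proportional) for PK,0.441,,0.436,0.354,0.505
sigma2_pc_add,(/mm3)^2,Variance of residual error (additive) for platelet count,25000,,24300,18800,29600
sigma2_anc_add,(/mm3)^2,Variance of residual error (additive) for neutrophil count,754,,748,613,839
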