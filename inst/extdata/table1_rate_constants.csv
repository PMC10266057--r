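ligand,buffer,temperature,Kd_app_nM,Kd_app_sd_nM,competitor,k_minus1P,k_minus1P_sd,k_thetaD,k_thetaD_sd,flags
r(GGAA)10[A488],BB_25,25,78,12,r(GGAA)10,NA,NA,NA,NA,prc2_5m;dissoc_in_deadtime
r(GGAA)10[A488],BB_25,4to25,NA,NA,r(GGAA)10,5.2e-4,0.5e-4,79,6.0,prc2_5m
r(G3A2)4[F],BB_10,25,2.3,0.35,ds-d(N)50,1.4e-3,1.1e-3,91,31,ligand_ge_2xKd;manual_baseline
r(G3A2)4[F],BB_10,4to25,NA,NA,r(G3A2)4,8.3e-4,1.6e-4,30,13,
r(G3A2)4[F],BB_10,4to25,NA,NA,ds-d(N)60,4.5e-4,0.15e-4,100,19,manual_baseline
r(G3A2)4[F],BB_25,25,4.4,0.34,r(G3A2)4,1.7e-3,0.60e-3,660,130,
r(G3A2)4[F],BB_25,4to25,NA,NA,r(G3A2)4,5.6e-4,0.50e-4,47,17,
r(G3A2)4[F],BB_25,4to25,NA,NA,r(G3A2)4,4.7e-4,NA,73,NA,carrier;single_experiment
r(G3A2)4[F],BB_100,25,1.4,0.15,NA,NA,NA,NA,NA,ligand_ge_2xKd
r(G3A2)4[F],BB_200,25,6.0,0.93,NA,NA,NA,NA,NA,
r(G3A2)4[A488],BB_25,25,8.2,0.69,NA,NA,NA,NA,NA,
r(G3A2)4[A488],BB_25,4to25,NA,NA,r(G3A2)4,8.8e-4,0.32e-4,59,20,
ds-[F]d(N)60,BB_10,25,5.1,0.60,r(G3A2)4,2.4e-3,0.25e-3,170,41,
ds-[F]d(N)60,BB_10,25,5.1,0.60,ds-d(N)60,9.1e-5,NA,260,NA,single_experiment
ds-[F]d(N)60,BB_10,4to25,NA,NA,r(G3A2)4,1.2e-3,0.062e-3,67,8.8,
ds-[F]d(N)60,BB_10,4to25,NA,NA,ds-d(N)60,5.3e-4,2.3e-4,150,21,
ds-[F]d(N)60,BB_25,25,82,13,NA,NA,NA,NA,NA,
ds-[F]d(N)60,BB_100,25,170,15,NA,NA,NA,NA,NA,
ds-[F]d(N)60,BB_200,25,NA,NA,NA,NA,NA,NA,NA,too_weak
ds-d(N)50[F],BB_10,25,5.0,0.46,r(G3A2)4,2.5e-3,0.11e-3,170,8.2,
ds-d(N)50[F],BB_10,25,5.0,0.46,ds-d(N)50,7.6e-4,0.75e-4,210,91,
ds-d(N)50[F],BB_10,4to25,NA,NA,ds-d(N)50,2.8e-4,NA,340,NA,single_experiment
ds-d(N)50[F],BB_25,25,390,31,NA,NA,NA,NA,NA,
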