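label,lake,condition,probe,atpct_mean,atpct_sd,atpct_n,biovol_um3,biovol_sd,biovol_n,percell_fmol_d,percell_sd,count_per_ml,total_biovol_um3_ml,population_umol_l_d,labeling_atpct,incubation_d
Crenothrix (Mgamma669),Rotsee,oxic,Mgamma669,NA,NA,NA,85,8.3,59,147.7,26.3,1.2e4,1.0e6,1.73,50,2
Crenothrix (Creno445),Rotsee,oxic,Creno445,22.00,4.8,17,73.7,8.4,51,128.0,22.8,9.2e3,6.8e5,1.18,50,2
Other gamma-MOB,Rotsee,oxic,Mgamma84+705,28.77,4.1,NA,4.2,NA,NA,10.6,0.9,2.6e4,1.1e5,0.27,50,2
Crenothrix (low O2),Zug,oxic low O2,Mgamma669,9.26,1.7,19,32.5,5.5,20,38.1,6.9,1.1e3,3.5e4,0.041,20,2
Crenothrix (high O2),Zug,oxic high O2,Mgamma669,8.68,1.9,10,32.5,5.5,20,35.3,7.8,1.1e3,3.5e4,0.038,20,2
Other gamma-MOB (low O2),Zug,oxic low O2,Mgamma84+705,10.39,3.1,NA,4.2,NA,NA,5.7,1.2,6.8e4,2.9e5,0.39,20,2
Other gamma-MOB (high O2),Zug,oxic high O2,Mgamma84+705,12.13,3.75,NA,4.2,NA,NA,6.9,1.6,6.8e4,2.9e5,0.47,20,2
Crenothrix (anoxic),Zug,anoxic nitrate,Mgamma669,13.27,4.9,6,49.7,20.3,15,74.2,26.6,0.4e3,2.0e4,0.03,20,2
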