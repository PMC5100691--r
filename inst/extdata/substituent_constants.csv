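"substituent","class","fragment","vdw_vol_inc","pi_inc","mr_inc","sigma_m","sigma_p","source"
"H","aryl","",0,0,1.03,0,0,"Hansch-Leo compilation"
"F","aryl","F",6.07,0.14,0.92,0.34,0.06,"Hansch-Leo compilation"
"Cl","aryl","Cl",15.21,0.71,6.03,0.37,0.23,"Hansch-Leo compilation"
"Br","aryl","Br",19.28,0.86,8.88,0.39,0.23,"Hansch-Leo compilation"
"I","aryl","I",25.28,1.12,13.94,0.35,0.18,"Hansch-Leo compilation"
"CH3","aryl","C",17.3,0.56,5.65,-0.07,-0.17,"Hansch-Leo compilation"
"C2H5","aryl","CC",34.6,1.02,10.3,-0.07,-0.15,"Hansch-Leo compilation"
"OCH3","aryl","CO",26.09,-0.02,7.87,0.12,-0.27,"Hansch-Leo compilation"
"CF3","aryl","FC(F)(F)",35.51,0.88,5.02,0.43,0.54,"Hansch-Leo compilation"
"OH","aryl","O",8.79,-0.67,2.85,0.12,-0.37,"Hansch-Leo compilation"
"NO2","aryl","[O-][N+](=O)",25.94,-0.28,7.36,0.71,0.78,"Hansch-Leo compilation"
"NH2","aryl","N",11,-1.23,5.42,-0.16,-0.66,"Hansch-Leo compilation"
"OCH2O","aryl","OCO-bridge",22.52,-0.05,5.89,-0.16,-0.16,"Hansch-Leo compilation (3,4-methylenedioxy, bridged)"
"H","alpha","",0,NA,NA,NA,NA,"computed, group-contribution volume backend"
"CH3","alpha","C",17.3,NA,NA,NA,NA,"computed, group-contribution volume backend"
"C2H5","alpha","CC",34.6,NA,NA,NA,NA,"computed, group-contribution volume backend"
"nC3H7","alpha","CCC",51.9,NA,NA,NA,NA,"computed, group-contribution volume backend"
"nC4H9","alpha","CCCC",69.2,NA,NA,NA,NA,"computed, group-contribution volume backend"
"iC4H9","alpha","CC(C)C",69.2,NA,NA,NA,NA,"computed, group-contribution volume backend"
"H","amine","N",0,NA,NA,NA,NA,"computed, group-contribution volume backend"
"CH3","amine","NC",17.3,NA,NA,NA,NA,"computed, group-contribution volume backend"
"diCH3","amine","N(C)C",34.6,NA,NA,NA,NA,"computed, group-contribution volume backend"
"C2H5","amine","NCC",34.6,NA,NA,NA,NA,"computed, group-contribution volume backend"
"tC4H9","amine","NC(C)(C)C",69.2,NA,NA,NA,NA,"computed, group-contribution volume backend"
"cC5H9","amine","NC1CCCC1",74.14,NA,NA,NA,NA,"computed, group-contribution volume backend"
"pyrrolidinyl","amine","N1CCCC1",56.84,NA,NA,NA,NA,"computed, group-contribution volume backend"
"piperidinyl","amine","N1CCCCC1",74.14,NA,NA,NA,NA,"computed, group-contribution volume backend"
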