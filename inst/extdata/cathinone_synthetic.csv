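"compound_id","smiles","ca_sub","n_sub","aryl_subs","ic50_A_nM","relation_A","ic50_B_nM","relation_B","is_exemplar"
"CATH-01","CC(C)CC(NC(C)(C)C)C(=O)c1ccc(Cl)cc1","iC4H9","tC4H9","4-Cl",10000,">",12.022,"=",FALSE
"CATH-02","CC(NCC)C(=O)c1cc(C)ccc1","CH3","C2H5","3-CH3",10000,">",83.9217,"=",FALSE
"CATH-03","CCCC(NCC)C(=O)c1ccc2c(c1)OCO2","nC3H7","C2H5","3,4-OCH2O",10000,">",36.24,"=",FALSE
"CATH-04","CCCC(N1CCCC1)C(=O)c1ccc(C(F)(F)F)cc1","nC3H7","pyrrolidinyl","4-CF3",676.681,"=",8.88008,"=",FALSE
"CATH-05","CCCCC(NCC)C(=O)c1ccc(F)cc1","nC4H9","C2H5","4-F",10000,">",15.2297,"=",FALSE
"CATH-06","CC(N1CCCCC1)C(=O)c1ccc(Cl)cc1","CH3","piperidinyl","4-Cl",1816.15,"=",171.43,"=",FALSE
"CATH-07","CCCCC(N(C)C)C(=O)c1cc(C)c(C)cc1","nC4H9","diCH3","3-CH3;4-CH3",1578.87,"=",1.42219,"=",FALSE
"CATH-08","CCC(NC)C(=O)c1cc(C)ccc1","C2H5","CH3","3-CH3",8620.81,"=",32.8366,"=",FALSE
"CATH-09","CC(N)C(=O)c1cc(C)c(C)cc1","CH3","H","3-CH3;4-CH3",10000,">",35.2649,"=",FALSE
"CATH-10","CCCC(N)C(=O)c1ccc(F)cc1","nC3H7","H","4-F",10000,">",4.39062,"=",FALSE
"CATH-11","CCCC(NC1CCCC1)C(=O)c1ccc(C)cc1","nC3H7","cC5H9","4-CH3",2792.01,"=",11.2541,"=",FALSE
"CATH-12","CCCCC(N(C)C)C(=O)c1ccc(C)cc1","nC4H9","diCH3","4-CH3",10000,">",5.66836,"=",FALSE
"CATH-13","CCCC(NC1CCCC1)C(=O)c1ccc(Br)cc1","nC3H7","cC5H9","4-Br",9505.51,"=",28.4933,"=",FALSE
"CATH-14","CC(NC1CCCC1)C(=O)c1ccccc1","CH3","cC5H9","",1e+05,">",727.074,"=",FALSE
"CATH-15","CC(C)CC(NC)C(=O)c1cc(C)c(C)cc1","iC4H9","CH3","3-CH3;4-CH3",3694.04,"=",2.50685,"=",FALSE
"CATH-16","CCCC(N)C(=O)c1cc(C)ccc1","nC3H7","H","3-CH3",4256.07,"=",3.9777,"=",FALSE
"CATH-17","CC(C)CC(N(C)C)C(=O)c1ccc(F)cc1","iC4H9","diCH3","4-F",10000,">",10.005,"=",FALSE
"CATH-18","CC(C)CC(N(C)C)C(=O)c1ccc(F)cc1","iC4H9","diCH3","4-F",10000,">",8.59315,"=",FALSE
"CATH-19","CC(C)CC(N1CCCCC1)C(=O)c1cc(C)ccc1","iC4H9","piperidinyl","3-CH3",1754.36,"=",2.69812,"=",FALSE
"CATH-20","CCCC(NC)C(=O)c1ccc(F)cc1","nC3H7","CH3","4-F",10000,">",13.1034,"=",FALSE
"CATH-21","CCC(N(C)C)C(=O)c1cc(C)c(C)cc1","C2H5","diCH3","3-CH3;4-CH3",10000,">",17.5494,"=",FALSE
"CATH-22","CC(N(C)C)C(=O)c1ccc(Br)cc1","CH3","diCH3","4-Br",3849,"=",50.2341,"=",FALSE
"CATH-23","CCCCC(NC1CCCC1)C(=O)c1cc(C)c(C)cc1","nC4H9","cC5H9","3-CH3;4-CH3",9209.52,"=",8.71232,"=",FALSE
"CATH-24","CC(C)CC(NC)C(=O)c1ccc(OC)cc1","iC4H9","CH3","4-OCH3",1e+05,">",6.88017,"=",FALSE
"CATH-25","CC(C)CC(NCC)C(=O)c1ccc(C(F)(F)F)cc1","iC4H9","C2H5","4-CF3",1e+05,">",34.7277,"=",FALSE
"CATH-26","CCC(N(C)C)C(=O)c1ccc(OC)cc1","C2H5","diCH3","4-OCH3",10000,">",53.7508,"=",FALSE
"CATH-27","CC(C)CC(NC1CCCC1)C(=O)c1ccccc1","iC4H9","cC5H9","",2431.34,"=",3.57991,"=",FALSE
"CATH-28","CCCCC(NC(C)(C)C)C(=O)c1cc(C)ccc1","nC4H9","tC4H9","3-CH3",10000,">",41.4538,"=",FALSE
"CATH-29","CC(C)CC(N1CCCC1)C(=O)c1cc(C)ccc1","iC4H9","pyrrolidinyl","3-CH3",757.406,"=",3.01699,"=",FALSE
"CATH-30","CCCC(N1CCCCC1)C(=O)c1ccc2c(c1)OCO2","nC3H7","piperidinyl","3,4-OCH2O",10000,">",124.753,"=",FALSE
"CATH-31","CCCC(N1CCCCC1)C(=O)c1cc(C)c(C)cc1","nC3H7","piperidinyl","3-CH3;4-CH3",862.557,"=",7.23276,"=",FALSE
"CATH-32","CCCCC(NC)C(=O)c1ccc2c(c1)OCO2","nC4H9","CH3","3,4-OCH2O",10000,">",4.02021,"=",FALSE
"CATH-33","CC(N1CCCCC1)C(=O)c1ccccc1","CH3","piperidinyl","",10000,">",426.185,"=",FALSE
"CATH-34","CCCC(N1CCCCC1)C(=O)c1ccc(OC)cc1","nC3H7","piperidinyl","4-OCH3",8154.66,"=",33.1514,"=",FALSE
"CATH-35","CCC(NCC)C(=O)c1ccc(F)cc1","C2H5","C2H5","4-F",10000,">",22.1936,"=",FALSE
"CATH-36","CC(C)CC(NC(C)(C)C)C(=O)c1ccc(Br)cc1","iC4H9","tC4H9","4-Br",3111.22,"=",11.2097,"=",FALSE
"CATH-37","CCC(N1CCCCC1)C(=O)c1cc(C)c(C)cc1","C2H5","piperidinyl","3-CH3;4-CH3",8788.89,"=",89.3471,"=",FALSE
"CATH-38","CCCCC(N)C(=O)c1ccccc1","nC4H9","H","",2223.81,"=",1.4474,"=",FALSE
"CATH-39","CC(NCC)C(=O)c1ccc(OC)cc1","CH3","C2H5","4-OCH3",1e+05,">",276.282,"=",FALSE
"CATH-40","CCC(N(C)C)C(=O)c1ccc(Br)cc1","C2H5","diCH3","4-Br",2760.83,"=",25.3968,"=",FALSE
"CATH-41","CCC(NC)C(=O)c1ccc(OC)cc1","C2H5","CH3","4-OCH3",10000,">",19.2668,"=",FALSE
"CATH-42","CCCC(NC1CCCC1)C(=O)c1ccc(OC)cc1","nC3H7","cC5H9","4-OCH3",4884.34,"=",11.9637,"=",FALSE
"CATH-43","CC(C)CC(NCC)C(=O)c1cc(C)ccc1","iC4H9","C2H5","3-CH3",3814.49,"=",2.15898,"=",FALSE
"CATH-44","CCC(N(C)C)C(=O)c1cc(C)ccc1","C2H5","diCH3","3-CH3",4214.32,"=",11.8366,"=",FALSE
"CATH-45","CCCCC(N(C)C)C(=O)c1ccc(Br)cc1","nC4H9","diCH3","4-Br",8059.48,"=",4.78192,"=",FALSE
"CATH-46","CC(NC)C(=O)c1ccc(C(F)(F)F)cc1","CH3","CH3","4-CF3",10000,">",120.598,"=",FALSE
"CATH-47","CCCC(NC)C(=O)c1ccc(Br)cc1","nC3H7","CH3","4-Br",5282.99,"=",16.151,"=",FALSE
"CATH-48","CCC(NC)C(=O)c1ccc(F)cc1","C2H5","CH3","4-F",10000,">",37.1896,"=",FALSE
"CATH-49","CCCCC(N1CCCCC1)C(=O)c1ccc(OC)cc1","nC4H9","piperidinyl","4-OCH3",4840.02,"=",6.52914,"=",FALSE
"CATH-50","CC(C)CC(NC(C)(C)C)C(=O)c1ccc(Cl)cc1","iC4H9","tC4H9","4-Cl",10000,">",22.1174,"=",FALSE
"CATH-51","CCCC(NC(C)(C)C)C(=O)c1cc(C)ccc1","nC3H7","tC4H9","3-CH3",10000,">",40.5473,"=",FALSE
"CATH-52","CC(N1CCCC1)C(=O)c1ccc(C)cc1","CH3","pyrrolidinyl","4-CH3",10000,">",185.157,"=",FALSE
"CATH-53","CC(C)CC(N(C)C)C(=O)c1ccc(Br)cc1","iC4H9","diCH3","4-Br",10000,">",3.15693,"=",FALSE
"CATH-54","CCC(NC)C(=O)c1ccccc1","C2H5","CH3","",10000,">",31.082,"=",FALSE
"CATH-55","CCCCC(N(C)C)C(=O)c1cc(C)ccc1","nC4H9","diCH3","3-CH3",10000,">",5.15048,"=",FALSE
"CATH-56","CC(C)CC(N1CCCC1)C(=O)c1ccccc1","iC4H9","pyrrolidinyl","",34500,"=",100,"=",TRUE
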