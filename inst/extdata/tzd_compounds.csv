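id,name,smiles,lp_inh_pct,lox_inh_pct,dpph_pct,abts_pct
1a,(Z)-5-(2-hydroxybenzylidene)thiazolidine-2.4-dione,Oc1ccccc1/C=C1\SC(=O)NC1=O,55.2,13.8,3.5,97.5
1b,(Z)-5-(4-hydroxy-3-methoxybenzylidene)thiazolidine-2.4-dione,COc1cc(/C=C2\SC(=O)NC2=O)ccc1O,36.5,8.5,27.9,99.7
1c,(Z)-5-(2.5-dihydroxybenzylidene)thiazolidine-2.4-dione,Oc1ccc(O)c(/C=C2\SC(=O)NC2=O)c1,61.6,76.3,16.5,97.6
1d,(Z)-5-(3-methoxybenzylidene)thiazolidine-2.4-dione,COc1cccc(/C=C2\SC(=O)NC2=O)c1,84.2,27.2,6.2,NA
1e,(Z)-5-(3-hydroxy-4-methoxybenzylidene)thiazolidine-2.4-dione,COc1ccc(/C=C2\SC(=O)NC2=O)cc1O,65.1,14.5,3.1,98.9
1f,(Z)-5-(3.4-dihydroxybenzylidene)thiazolidine-2.4-dione,Oc1ccc(/C=C2\SC(=O)NC2=O)cc1O,50.4,13.4,57.6,100.0
1g,(Z)-5-(3.4.5-trimethoxybenzylidene)thiazolidine-2.4-dione,COc1cc(/C=C2\SC(=O)NC2=O)cc(OC)c1OC,46.3,7.3,3.3,NA
1h,(Z)-5-(2.5-dimethoxybenzylidene)thiazolidine-2.4-dione,COc1ccc(OC)c(/C=C2\SC(=O)NC2=O)c1,62.4,17.6,4.2,NA
1i,(Z)-5-(3-bromobenzylidene)thiazolidine-2.4-dione,Brc1cccc(/C=C2\SC(=O)NC2=O)c1,49.2,7.7,3.1,NA
1j,(Z)-5-(2-hydroxy-5-nitrobenzylidene)thiazolidine-2.4-dione,O=[N+]([O-])c1ccc(O)c(/C=C2\SC(=O)NC2=O)c1,76.9,18.3,9.6,49.3
1k,(Z)-5-(2-methoxybenzylidene)thiazolidine-2.4-dione,COc1ccccc1/C=C1\SC(=O)NC1=O,55.9,30.31,3.8,NA
1l,(Z)-5-(3-hydroxybenzylidene)thiazolidine-2.4-dione,Oc1cccc(/C=C2\SC(=O)NC2=O)c1,68.2,20.2,10.7,84.7
1m,(Z)-5-(4-hydroxybenzylidene)thiazolidine-2.4-dione,Oc1ccc(/C=C2\SC(=O)NC2=O)cc1,69.5,12.7,3.8,94.8
1n,(Z)-5-(4-(dimethylamino)benzylidene)thiazolidine-2.4-dione,CN(C)c1ccc(/C=C2\SC(=O)NC2=O)cc1,23.0,12.5,7.6,74.7
1o,(Z)-5-(4-(benzyloxy)-2-hydroxybenzylidene)thiazolidine-2.4-dione,Oc1cc(OCc2ccccc2)ccc1/C=C1\SC(=O)NC1=O,50.0,34.7,NA,100.0
1p,(Z)-5-(3-fluorobenzylidene)thiazolidine-2.4-dione,Fc1cccc(/C=C2\SC(=O)NC2=O)c1,46.0,12.9,9.4,NA
1q,(Z)-5-(2.4-dimethoxybenzylidene)thiazolidine-2.4-dione,COc1ccc(/C=C2\SC(=O)NC2=O)c(OC)c1,59.9,19.2,4.7,6.6
1r,(Z)-5-benzylidenethiazolidine-2.4-dione,c1ccccc1/C=C1\SC(=O)NC1=O,56.7,18.8,3.6,NA
1s,(Z)-5-((1H-indol-3-yl)methylene)thiazolidine-2.4-dione,O=C1NC(=O)S/C1=C\c1c[nH]c2ccccc12,82.9,71.1,2.7,84.2
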