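polarity,feature,measured_mz,rt_s,compound,base,rules,isotope_k,identity
pos,M216T214,216.1383,214,PBP,[M+H]+,dehydro-,0,artifact (dehydro-)
pos,M217T214,217.1415,214,PBP,[M+H]+,dehydro-,1,artifact (dehydro-) 13C-isotope
pos,M218T216,218.1540,216,PBP,[M+H]+,,0,parent
pos,M219T216,219.1572,216,PBP,[M+H]+,,1,parent 13C-isotope
pos,M220T226,220.1695,226,PBP,[M+H]+,dihydro-,0,M (dihydro-)
pos,M221T226,221.1728,226,PBP,[M+H]+,dihydro-,1,M (dihydro-) 13C-isotope
pos,M232T343,232.1331,343,PBP,[M+H]+,oxo-,0,M (oxo-)
pos,M236T214,236.1643,214,PBP,[M+H]+,dihydro-HO-,0,M (dihydro-HO-)
pos,M237T214,237.1676,214,PBP,[M+H]+,dihydro-HO-,1,M (dihydro-HO-) 13C-isotope
pos,M250T215,250.1435,215,PBP,[M+H]+,di-HO-,0,M (di-HO-)
pos,M215T328,215.1542,328,PBP,[M+H]+,dehydro-;imido-,0,impurity (dehydro-) artifact (imido-)
pos,M216T114,216.1383,114,PBP,[M+H]+,dehydro-,0,impurity (dehydro-)
pos,M216T347,216.1383,347,PBP,[M+H]+,dehydro-,0,artifact (dehydro-)
pos,M218T351,218.1541,351,PBP,[M+H]+,,0,parent
pos,M219T350,219.1572,350,PBP,[M+H]+,,1,parent 13C-isotope
pos,M220T355,220.1694,355,PBP,[M+H]+,dihydro-,0,M (dihydro-)
pos,M221T355,221.1726,355,PBP,[M+H]+,dihydro-,1,M (dihydro-) 13C-isotope
pos,M234T114,234.1488,114,PBP,[M+H]+,dihydro-oxo-,0,M (dihydro-oxo-)
pos,M236T367,236.1643,367,PBP,[M+H]+,dihydro-HO-,0,M (dihydro-HO-)
pos,M237T367,237.1677,367,PBP,[M+H]+,dihydro-HO-,1,M (dihydro-HO-) 13C-isotope
pos,M243T80,243.1492,80,PBP,[M+H]+,dehydro-;cyano-,0,impurity (dehydro-) artifact (cyano-)
pos,M250T412,250.1436,412,PBP,[M+H]+,di-HO-,0,M (di-HO-)
pos,M471T350,471.2771,350,PBP,[2M+2H+Cl]+,,0,adduct [2M+2H+Cl]+
pos,M472T350,472.2805,350,PBP,[2M+2H+Cl]+,,1,adduct [2M+2H+Cl]+ 13C-isotope
pos,M206T296,206.1538,296,PEP,[M+H]+,"N,N-dealkyl-",0,"M (N,N-dealkyl-)"
pos,M258T312,258.1852,312,PEP,[M+H]+,dehydro-,0,artifact (dehydro-)
pos,M260T296,260.2008,296,PEP,[M+H]+,,0,parent conformer 2
pos,M260T312,260.2009,312,PEP,[M+H]+,,0,parent conformer 1
pos,M261T312,261.2042,312,PEP,[M+H]+,,1,parent 13C-isotope
pos,M262T312,262.2073,312,PEP,[M+H]+,,2,parent 13C2-isotope
pos,M262T325,262.2165,325,PEP,[M+H]+,dihydro-,0,M (dihydro-)
pos,M263T324,263.2197,324,PEP,[M+H]+,dihydro-,1,M (dihydro-) 13C-isotope
pos,M274T425,274.1799,425,PEP,[M+H]+,oxo-,0,M (oxo-)
pos,M276T229,276.1958,229,PEP,[M+H]+,HO-,0,M (HO-) isomer 2
pos,M277T229,277.1990,229,PEP,[M+H]+,HO-,1,M (HO-) isomer 2 13C-isotope
pos,M278T307,278.2113,307,PEP,[M+H]+,dihydro-HO-,0,M (dihydro-HO-)
pos,M292T310,292.1904,310,PEP,[M+H]+,di-HO-,0,M (di-HO-)
pos,M246T254,246.1849,254,PHP,[M+H]+,,0,shorter-chain homologue impurity
pos,M257T216,257.2008,216,PEP,[M+H]+,dehydro-;imido-,0,impurity (dehydro-) artifact (imido-)
pos,M258T198,258.1849,198,PEP,[M+H]+,dehydro-,0,impurity (dehydro-)
pos,M258T216,258.2042,216,PEP,[M+H]+,dehydro-;imido-,1,impurity (dehydro-) artifact (imido-) 13C-isotope
pos,M258T249,258.1849,249,PEP,[M+H]+,dehydro-,0,artifact (dehydro-)
pos,M260T243,260.2007,243,PEP,[M+H]+,,0,parent conformer 1
pos,M260T276,260.2005,276,PEP,[M+H]+,,0,parent conformer 2
pos,M261T243,261.2040,243,PEP,[M+H]+,,1,parent 13C-isotope
pos,M262T243,262.2071,243,PEP,[M+H]+,,2,parent 13C2-isotope
pos,M262T271,262.2162,271,PEP,[M+H]+,dihydro-,0,M (dihydro-) diastereomer 1
pos,M262T282,262.2162,282,PEP,[M+H]+,dihydro-,0,M (dihydro-) diastereomer 2
pos,M263T270,263.2195,270,PEP,[M+H]+,dihydro-,1,M (dihydro-) diastereomer 1 13C-isotope
pos,M263T282,263.2195,282,PEP,[M+H]+,dihydro-,1,M (dihydro-) diastereomer 2 13C-isotope
pos,M272T87,272.1641,87,PEP,[M+H]+,oxo-HO-;-H2O,0,M (oxo-HO-) isomer 2 water-loss artifact
pos,M276T90,276.1954,90,PEP,[M+H]+,dihydro-oxo-,0,M (dihydro-oxo-)
pos,M276T269,276.1954,269,PEP,[M+H]+,HO-,0,M (HO-) isomer 1
pos,M276T316,276.1954,316,PEP,[M+H]+,HO-,0,M (HO-) isomer 2
pos,M277T269,277.1987,269,PEP,[M+H]+,HO-,1,M (HO-) isomer 1 13C-isotope
pos,M277T316,277.1987,316,PEP,[M+H]+,HO-,1,M (HO-) isomer 2 13C-isotope
pos,M278T291,278.2110,291,PEP,[M+H]+,dihydro-HO-,0,M (dihydro-HO-)
pos,M285T74,285.1957,74,PEP,[M+H]+,dehydro-;cyano-,0,impurity (dehydro-) artifact (cyano-)
pos,M290T93,290.1746,93,PEP,[M+H]+,oxo-HO-,0,M (oxo-HO-) isomer 1
pos,M292T321,292.1901,321,PEP,[M+H]+,di-HO-,0,M (di-HO-)
neg,M327T82,327.2323,82,DHA,[M-H]-,,0,docosahexaenoic acid
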