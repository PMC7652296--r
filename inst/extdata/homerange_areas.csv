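colony,colony_50p,colony_90p,ind_mean_50p,ind_sd_50p,ind_mean_90p,ind_sd_90p
Chowiet,1415726,5120609,866352,875273,2875308,2643150
Middleton,627880,3106851,338206,266197,1075572,825712
St. Lazaria,408793,2428101,420982,355115,1399460,1147132
Lucy,650667,2311713,502806,486398,1610695,1550292
S'Gang Gwaay,637480,2313936,423452,394763,1409576,1303438
Triangle,837116,2687246,473992,378839,1496879,1150994
Pine,404399,1505507,136205,125384,468058,377293
Cleland,490341,1746645,275473,328310,989485,1107242
Protection,1044610,3948580,322455,271926,1091980,839139
Destruction,121136,429640,87846,7867,350103,65891
Farallones,69851,324594,66589,30521,288058,118205
Año Nuevo,136904,680534,67809,120074,292267,433373
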