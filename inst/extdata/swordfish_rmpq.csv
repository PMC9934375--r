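taxon,W_g,pW,N,pN,F,pF,GII,pGII,IRI,pIRI,pPSIRI
"Jumbo squid, Dosidicus gigas",131892.7,53.27,1061,20.23,173,59.25,76.64,44.25,4354.96,56.47,36.75
"Boreopacific gonate squid, Gonatopsis borealis",19949.8,8.06,884,16.86,182,62.33,50.37,29.08,1552.94,20.14,12.46
"Abraliopsis sp.",45.1,0.02,464,8.85,117,40.07,28.25,16.31,355.26,4.61,4.44
"Gonatus spp.",181.6,0.07,299,5.7,110,37.67,25.08,14.48,217.56,2.82,2.89
"Market squid, Doryteuthis opalescens",1447.6,0.58,538,10.26,88,30.14,23.66,13.66,326.81,4.24,5.42
"Pacific hake, Merluccius productus",36360.1,14.69,331,6.31,49,16.78,21.81,12.59,352.37,4.57,10.50
"Duckbill barracudina, Magnisudis atlantica",4568.6,1.85,218,4.16,84,28.77,20.07,11.59,172.67,2.24,3.01
"Unidentified Teleostei",2316.9,0.94,119,2.27,65,22.26,14.7,8.49,71.35,0.93,1.61
"Chubby pearleye, Rosenblattichthys volucris",810.6,0.33,166,3.17,49,16.78,11.71,6.76,58.61,0.76,1.75
"Jack mackerel, Trachurus symmetricus",6668.2,2.69,72,1.37,28,9.59,7.88,4.55,38.99,0.51,2.03
"Nansenia spp.",510.9,0.21,124,2.36,32,10.96,7.81,4.51,28.17,0.37,1.29
"Onychoteuthis borealijaponica",656.6,0.27,60,1.14,35,11.99,7.73,4.47,16.89,0.22,0.71
"Slender barracudina, Lestidiops ringens",330,0.13,92,1.75,29,9.93,6.82,3.94,18.75,0.24,0.94
"Pacific pomfret, Brama japonica",5241.6,2.12,41,0.78,24,8.22,6.42,3.71,23.83,0.31,1.45
"Pacific sardine, Sardinops sagax",1823.1,0.74,77,1.47,26,8.9,6.41,3.7,19.63,0.25,1.11
"Luvar, Luvarus imperialis",19258.5,7.78,18,0.34,7,2.4,6.07,3.51,19.47,0.25,4.06
"Pacific saury, Cololabis saira",1366.8,0.55,76,1.45,21,7.19,5.31,3.06,14.39,0.19,1.00
"Unidentified Scopelarchidae",476.9,0.19,86,1.64,20,6.85,5.01,2.89,12.55,0.16,0.92
"Cock-eyed squid, Histioteuthis heteropsis",1312.2,0.53,52,0.99,18,6.16,4.44,2.56,9.38,0.12,0.76
"Pacific mackerel, Scomber japonicus",2180.7,0.88,66,1.26,16,5.48,4.4,2.54,11.72,0.15,1.07
"Sunbeam lampfish, Lampadena urophaos",201.9,0.08,42,0.8,18,6.16,4.07,2.35,5.44,0.07,0.44
"King-of-the-salmon, Trachipterus altivelis",5577.4,2.25,25,0.48,13,4.45,3.86,2.39,10.59,0.16,1.37
"Flowervase jewell squid, Histioteuthis dofleini",560.1,0.23,25,0.48,15,5.14,3.37,1.95,3.61,0.05,0.36
"Unidentified Eucarida",5.5,<0.01,154,2.94,6,2.05,2.88,1.67,6.04,0.08,1.48
"Unidentified Teuthoidea",202,0.08,15,0.29,12,4.11,2.58,1.49,1.51,0.02,0.19
"Spotted barracudina, Arctozenus risso",67.9,0.03,14,0.27,8,2.74,1.75,1.01,0.81,0.01,0.15
"Histioteuthis spp.",56.7,0.02,9,0.17,8,2.74,1.69,0.98,0.53,0.01,0.10
"Argonauta sp.",13.1,0.01,8,0.15,8,2.74,1.67,0.97,0.43,0.01,0.08
"Striped mullet, Mugil cephalus",1737.8,0.7,8,0.15,4,1.37,1.28,0.74,1.17,0.02,0.43
"Octopoteuthis sp.",2.1,<0.01,6,0.11,6,2.05,1.25,0.72,0.24,<0.01,0.06
"Bigfin lampfish, Symbolophorus californiensis",5.4,<0.01,7,0.13,5,1.71,1.07,0.62,0.23,<0.01,0.07
"Sharpchin barracudina, Stemonosudis macrura",8.8,<0.01,8,0.15,4,1.37,0.88,0.51,0.21,<0.01,0.08
"Cranchia scabra",4.5,<0.01,5,0.1,4,1.37,0.85,0.49,0.13,<0.01,0.06
"Mexican lampfish, Triphoturus mexicanus",<0.1,<0.01,4,0.08,4,1.37,0.83,0.49,0.1,<0.01,0.05
"Paralepididae, Barracudinas",111.3,0.04,7,0.13,3,2.4,1.49,0.86,0.43,0.01,0.09
"Unidentified Euphausiidae",3,<0.01,6,0.11,3,2.05,1.25,0.72,0.24,<0.01,0.06
"Robust clubhook squid, Onykia robusta",43.3,0.02,4,0.08,3,1.37,0.85,0.49,0.13,<0.01,0.05
"Northern anchovy, Engraulis mordax",1.6,<0.01,4,0.08,3,1.37,0.84,0.49,0.11,<0.01,0.05
"California smoothtongue, Leuroglossus stilbius",<0.1,<0.01,4,0.08,3,1.37,0.83,0.49,0.1,<0.01,0.05
"Unidentified Tunicata",3.5,<0.01,3,0.06,3,1.03,0.63,0.37,0.06,<0.01,0.04
"Smalleye squaretail, Tetragonurus cuvieri",161.9,0.07,3,0.06,2,1.03,0.66,0.39,0.13,<0.01,0.07
"Onychoteuthis sp.",<0.1,<0.01,4,0.08,2,1.37,0.83,0.49,0.1,<0.01,0.05
"Japetella sp.",<0.1,<0.01,4,0.08,2,1.37,0.83,0.49,0.1,<0.01,0.05
"Splitnose rockfish, Sebastes diploproa",924.2,0.37,2,0.04,1,0.68,0.63,0.36,0.28,<0.01,0.21
"Northern lampfish, Stenobrachius leucopsarus",<0.1,<0.01,2,0.04,2,0.68,0.42,0.24,0.03,<0.01,0.03
"Octopus rubescens",<0.1,<0.01,2,0.04,2,0.68,0.42,0.24,0.03,<0.01,0.03
"Chiroteuthis calyx",<0.1,<0.01,2,0.04,2,0.68,0.42,0.24,0.03,<0.01,0.03
"Albacore, Thunnus alalunga",371.6,0.15,1,0.02,1,0.34,0.3,0.17,0.06,<0.01,0.09
"Sebastes spp.",3,<0.01,8,0.15,1,2.74,1.67,0.97,0.42,0.01,0.08
"Halfmoon, Medialuna californiensis",81,0.03,1,0.02,1,0.34,0.23,0.13,0.02,<0.01,0.03
"Dogtooth lampfish, Ceratoscopelus townsendi",1.5,<0.01,2,0.04,1,0.68,0.42,0.24,0.03,<0.01,0.03
"Shortbelly rockfish, Sebastes jordani",0.4,<0.01,2,0.04,1,0.68,0.42,0.24,0.03,<0.01,0.03
"Leachia dislocata",<0.1,<0.01,2,0.04,1,0.68,0.42,0.24,0.03,<0.01,0.03
"Pacific bonito, Sarda chiliensis",25.8,0.01,1,0.02,1,0.34,0.21,0.12,0.01,<0.01,0.02
"Auxis sp.",4.7,<0.01,1,0.02,1,0.34,0.21,0.12,0.01,<0.01,0.02
"Mastigoteuthis dentata",<0.1,<0.01,1,0.02,1,0.34,0.21,0.12,0.01,<0.01,0.02
"Octopus spp.",<0.1,<0.01,1,0.02,1,0.34,0.21,0.12,0.01,<0.01,0.02
"California flashlightfish, Protomyctophum crockeri",<0.1,<0.01,1,0.02,1,0.34,0.21,0.12,0.01,<0.01,0.02
"California headlightfish, Diaphus theta",<0.1,<0.01,1,0.02,1,0.34,0.21,0.12,0.01,<0.01,0.02
"Unidentified Isopoda",<0.1,<0.01,1,0.02,1,0.34,0.21,0.12,0.01,<0.01,0.02
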