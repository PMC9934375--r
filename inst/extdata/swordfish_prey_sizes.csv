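taxon,n,size_min,size_max,mean_mm,median_mm
"Jumbo squid, Dosidicus gigas",113,90,650,292,280
"Pacific hake, Merluccius productus",76,180,475,356,376
"Boreopacific gonate squid, Gonatopsis borealis",23,110,285,199,192
"Duckbill barracudina, Magnisudis atlantica",21,225,370,284,275
"Pacific saury, Cololabis saira",19,170,275,212,215
"Market squid, Doryteuthis opalescens",15,90,120,105,105
"Pacific pomfret, Brama japonica",11,106,380,270,270
"Luvar, Luvarus imperialis",8,445,550,516,522
"King-of-the-salmon, Trachipterus altivelis",6,100,360,246,285
"Jack mackerel, Trachurus symmetricus",5,195,530,355,310
"Slender barracudina, Lestidiops ringens",4,190,200,197,200
"Pacific mackerel, Scomber japonicus",4,170,260,230,245
"Chubby pearleye, Rosenblattichthys volucris",4,180,210,191,187
"Pacific sardine, Sardinops sagax",4,175,245,208,206
"Flowervase jewell squid, Histioteuthis dofleini",3,160,220,182,165
"Nansenia spp.",2,265,270,267,267
"Onychoteuthis sp.",2,165,270,217,217
"Splitnose rockfish, Sebastes diploproa",2,290,310,300,300
"Smalleye squaretail, Tetragonurus cuvieri",2,125,132,128,128
"Cock-eyed squid, Histioteuthis heteropsis",2,150,210,180,180
"Spotted barracudina, Arctozenus risso",1,230,230,,
"Halfmoon, Medialuna californiensis",1,210,210,,
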