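common_name,scientific_name,salmon_added,in_original_ohi
Lobster,Homarus americanus,FALSE,FALSE
Leather star,Dermasterias imbricata,FALSE,FALSE
Atlantic Cod,Gadus morhua,FALSE,FALSE
Chum Salmon,Oncorhynchus keta,TRUE,FALSE
Coho Salmon,Oncorhynchus kisutch,TRUE,FALSE
Pink Salmon,Oncorhynchus gorbuscha,TRUE,FALSE
Rainbow Trout,Oncorhynchus mykiss,FALSE,FALSE
Sockeye Salmon,Oncorhynchus nerka,FALSE,FALSE
Chinook Salmon,Oncorhynchus tshawytscha,TRUE,FALSE
Atlantic Salmon,Salmo salar,FALSE,FALSE
Arctic Char,Salvelinus alpinus,FALSE,FALSE
Orca,Orcinus orca,FALSE,FALSE
Humpback,Megaptera novaeangliae,FALSE,TRUE
Bowhead,Balaena mysticetus,FALSE,TRUE
Blue whale,Balaenoptera musculus,FALSE,TRUE
Beluga,Delphinapterus leucas,FALSE,FALSE
Polar Bear,Ursus maritimus,FALSE,TRUE
Common Loon,Gavia immer,FALSE,FALSE
Bald Eagle,Haliaeetus leucocephalus,FALSE,FALSE
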