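(Callorhinchus_milii,(Lepisosteus_oculatus,((Danio_rerio,Oryzias_latipes,Takifugu_rubripes,Gasterosteus_aculeatus)Teleostei,(Latimeria_chalumnae,(Xenopus_tropicalis,((Anolis_carolinensis,Pelodiscus_sinensis,(Gallus_gallus,Meleagris_gallopavo,Taeniopygia_guttata)Aves)Sauria,(Ornithorhynchus_anatinus,(Monodelphis_domestica,((Equus_caballus,(Bos_taurus,Sus_scrofa,Ovis_aries)Cetartiodactyla,(Canis_familiaris,Felis_catus)Carnivora)Laurasiatheria,((Oryctolagus_cuniculus,Mus_musculus,Rattus_norvegicus)Glires,(Microcebus_murinus,Callithrix_jacchus,Macaca_mulatta,(Homo_sapiens,Pan_troglodytes,Gorilla_gorilla)Hominidae)Primates)Euarchontoglires)Eutheria)Theria)Mammalia)Amniota)Tetrapoda)Sarcopterygii))Osteichthyes)Vertebrata;
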