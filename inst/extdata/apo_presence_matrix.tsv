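taxon	ApoA-I	ApoA-II	ApoA-IV	ApoA-V	ApoC-I	ApoC-IA	ApoC-II	ApoC-III	ApoC-IV	ApoE
Callorhinchus_milii	1	0	1	0	0	0	0	0	0	0
Lepisosteus_oculatus	1	1	1	0	0	0	0	0	0	0
Danio_rerio	1	1	1	0	1	0	1	0	0	0
Oryzias_latipes	1	1	1	0	1	0	1	0	0	0
Takifugu_rubripes	1	1	1	0	1	0	1	0	0	0
Gasterosteus_aculeatus	1	1	1	0	1	0	1	0	0	0
Latimeria_chalumnae	1	1	1	0	1	0	1	0	0	1
Xenopus_tropicalis	1	1	1	1	1	0	1	0	0	1
Anolis_carolinensis	1	1	1	1	1	0	1	1	0	1
Pelodiscus_sinensis	1	1	1	1	1	0	1	1	0	1
Gallus_gallus	1	1	1	1	0	0	0	1	0	0
Meleagris_gallopavo	1	1	1	1	0	0	0	1	0	0
Taeniopygia_guttata	1	1	1	1	0	0	0	1	0	0
Ornithorhynchus_anatinus	1	1	1	0	0	0	1	1	0	1
Monodelphis_domestica	1	1	1	1	1	0	1	1	0	1
Equus_caballus	1	1	1	1	1	0	1	1	1	1
Bos_taurus	1	1	1	1	0	0	1	1	1	1
Sus_scrofa	1	1	1	1	0	0	1	1	1	1
Ovis_aries	1	1	1	1	0	0	1	1	1	1
Canis_familiaris	1	1	1	1	1	0	1	1	1	1
Felis_catus	1	1	1	1	1	0	1	1	1	1
Oryctolagus_cuniculus	1	1	1	1	1	0	1	1	1	1
Mus_musculus	1	1	1	1	1	0	1	1	1	1
Rattus_norvegicus	1	1	1	1	1	0	1	1	1	1
Microcebus_murinus	1	1	1	1	1	1	1	1	1	1
Callithrix_jacchus	1	1	1	1	1	1	1	1	1	1
Macaca_mulatta	1	1	1	1	1	1	1	1	1	1
Homo_sapiens	1	1	1	1	1	0	1	1	1	1
Pan_troglodytes	1	1	1	1	1	1	1	1	1	1
Gorilla_gorilla	1	1	1	1	1	1	1	1	1	1
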