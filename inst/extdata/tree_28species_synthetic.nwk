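(((((((((((((((Homo_sapiens:7,Pan_troglodytes:7):9,Pongo_abelii:16):74,Mus_musculus:90):69,Monodelphis_domestica:159):18,Ornithorhynchus_anatinus:177):142,(Gallus_gallus:280,Anolis_carolinensis:280):39):33,Xenopus_tropicalis:352):83,(Danio_rerio:230,Gasterosteus_aculeatus:230):205):130,Ciona_savignyi:565):135,((Drosophila_melanogaster:590,Caenorhabditis_elegans:590):30,Schistosoma_mansoni:620):80):405,(((Saccharomyces_cerevisiae:460,Neurospora_crassa:460):130,Schizosaccharomyces_pombe:590):70,Ustilago_maydis:660):445):195,Dictyostelium_discoideum:1300):200,(((Vitis_vinifera:117,Arabidopsis_thaliana:117):43,Oryza_sativa:160):336,Physcomitrella_patens:496):1004):80,((Phaeodactylum_tricornutum:450,Phytophthora_infestans:450):750,Plasmodium_falciparum:1200):380):188,Leishmania_major:1768);
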