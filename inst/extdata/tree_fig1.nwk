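((((Eumenes_fraternus:0.03703703704,Eumenes_tripunctatus:0.03703703704):0.07407407407,(Euodynerus_megaera:0.03703703704,Monobia_quandridens:0.03703703704):0.07407407407):0.1481481481,(Polistes_metricus:0.1111111111,((Vespula_germanica:0.03703703704,Vespula_maculifrons:0.03703703704):0.03703703704,Vespula_squamosa:0.07407407407):0.03703703704):0.1481481481):0.7407407407,(((Sceliphron_caementarium:0.03703703704,Sceliphron_laetum:0.03703703704):0.07407407407,(Ammophila_sp_JC134:0.03703703704,Sphex_lucae:0.03703703704):0.07407407407):0.5925925926,((((Bembix_americana:0.03703703704,Bembix_dentilabris:0.03703703704):0.03703703704,Bembix_amoena:0.07407407407):0.1111111111,(Oxybelus_abdominalis:0.07407407407,(Philanthus_gibbosus:0.03703703704,Philanthus_sp_CSM2006:0.03703703704):0.03703703704):0.1111111111):0.3703703704,((Xylocopa_pubescens:0.2222222222,((Amegilla_asserta:0.03703703704,Anthophora_montana:0.03703703704):0.1481481481,(Apis_mellifera:0.1111111111,(Bombus_diversus:0.07407407407,(Bombus_ardens:0.03703703704,Bombus_mendax:0.03703703704):0.03703703704):0.03703703704):0.07407407407):0.03703703704):0.1111111111,(Anthidium_porterae:0.07407407407,(Megachile_pugnata:0.03703703704,Osmia_lignaria:0.03703703704):0.03703703704):0.2592592593):0.2222222222):0.1481481481):0.2962962963);
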