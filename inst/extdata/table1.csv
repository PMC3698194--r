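species,tree_name,family,diet,manipulation,body_mass_g,thorax_mass_g,fmr,wing_area_cm2,wing_loading_g_cm2,head_width_mm,source
Amegilla dawsoni,Amegilla_asserta,Apidae,pollen,1,0.700,,,,0.31,,literature
Anthophora sp.,Anthophora_montana,Apidae,pollen,1,0.133,,0.396,,0.183,,this study
Apis mellifera,Apis_mellifera,Apidae,pollen,1,0.094,,0.358,,0.170,,this study
Bombus impatiens,Bombus_diversus,Apidae,pollen,1,0.201,,0.261,,0.287,,literature
Bombus sp. 1,Bombus_ardens,Apidae,pollen,1,0.208,,0.374,,0.220,,this study
Bombus sp. 2,Bombus_mendax,Apidae,pollen,1,0.204,,0.401,,0.199,,this study
Xylocopa varipuncta,Xylocopa_pubescens,Apidae,pollen,1,0.838,,0.342,,0.331,,literature
Anthidium manicatum,Anthidium_porterae,Megachilidae,pollen,1,0.154,,0.344,,0.205,,this study
Megachile rotundata,Megachile_pugnata,Megachilidae,pollen,1,0.102,,0.32,,0.178,,this study
Osmia rufa,Osmia_lignaria,Megachilidae,pollen,1,0.187,,0.353,,0.223,,this study
Ammophila sabulosa,Ammophila_sp_JC134,Sphecidae,prey,0,0.026,,0.409,,0.075,,this study
Sceliphron curvatum,Sceliphron_caementarium,Sphecidae,prey,0,0.083,,0.46,,0.094,,this study
Sceliphron destillatorium,Sceliphron_laetum,Sphecidae,prey,0,0.181,,0.44,,0.124,,this study
Sphex rufocinctus,Sphex_lucae,Sphecidae,prey,0,0.118,,0.426,,0.109,,this study
Bembix olivacea,Bembix_americana,Crabronidae,prey,0,0.109,,0.46,,0.122,,this study
Bembix sinuata,Bembix_dentilabris,Crabronidae,prey,0,0.158,,0.456,,0.195,,this study
Bembix troglodytes,Bembix_amoena,Crabronidae,prey,0,0.099,,0.36,,,,literature
Oxybelus sp.,Oxybelus_abdominalis,Crabronidae,prey,0,0.008,,0.374,,0.087,,this study
Philanthus pulchellus,Philanthus_gibbosus,Crabronidae,prey,0,0.043,,0.392,,0.08,,this study
Philanthus triangulum,Philanthus_sp_CSM2006,Crabronidae,prey,0,0.092,,0.401,,0.116,,this study
Polistes dominulus,Polistes_metricus,Vespidae,prey,1,0.065,,0.369,,0.085,,this study
Vespula germanica,Vespula_germanica,Vespidae,prey,1,0.067,,0.361,,,,literature
Vespula maculifrons,Vespula_maculifrons,Vespidae,prey,1,0.038,,0.381,,,,literature
Vespula vulgaris,Vespula_squamosa,Vespidae,prey,1,0.078,,0.344,,0.139,,this study
Eumenes sp. 1,Eumenes_fraternus,Vespidae,prey,0,0.048,,0.403,,0.078,,this study
Eumenes sp. 2,Eumenes_tripunctatus,Vespidae,prey,0,0.042,,0.375,,0.098,,this study
Euodynerus sp.,Euodynerus_megaera,Vespidae,prey,0,0.049,,0.363,,0.067,,this study
Monobia quandridens,Monobia_quandridens,Vespidae,prey,0,0.218,,0.385,,,,literature
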