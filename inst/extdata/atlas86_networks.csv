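region_name,network
lh_bankssts,DMN
lh_caudalanteriorcingulate,VAN
lh_caudalmiddlefrontal,DAN
lh_cuneus,VIS
lh_entorhinal,LIM
lh_fusiform,VIS
lh_inferiorparietal,FP
lh_inferiortemporal,DMN
lh_isthmuscingulate,DMN
lh_lateraloccipital,VIS
lh_lateralorbitofrontal,LIM
lh_lingual,VIS
lh_medialorbitofrontal,LIM
lh_middletemporal,DMN
lh_paracentral,SOM
lh_parahippocampal,LIM
lh_parsopercularis,VAN
lh_parsorbitalis,FP
lh_parstriangularis,FP
lh_pericalcarine,VIS
lh_postcentral,SOM
lh_posteriorcingulate,DMN
lh_precentral,SOM
lh_precuneus,DMN
lh_rostralanteriorcingulate,DMN
lh_rostralmiddlefrontal,FP
lh_superiorfrontal,DMN
lh_superiorparietal,DAN
lh_superiortemporal,SOM
lh_supramarginal,VAN
lh_frontalpole,DMN
lh_temporalpole,LIM
lh_transversetemporal,SOM
lh_insula,VAN
rh_bankssts,DMN
rh_caudalanteriorcingulate,VAN
rh_caudalmiddlefrontal,DAN
rh_cuneus,VIS
rh_entorhinal,LIM
rh_fusiform,VIS
rh_inferiorparietal,FP
rh_inferiortemporal,DMN
rh_isthmuscingulate,DMN
rh_lateraloccipital,VIS
rh_lateralorbitofrontal,LIM
rh_lingual,VIS
rh_medialorbitofrontal,LIM
rh_middletemporal,DMN
rh_paracentral,SOM
rh_parahippocampal,LIM
rh_parsopercularis,VAN
rh_parsorbitalis,FP
rh_parstriangularis,FP
rh_pericalcarine,VIS
rh_postcentral,SOM
rh_posteriorcingulate,DMN
rh_precentral,SOM
rh_precuneus,DMN
rh_rostralanteriorcingulate,DMN
rh_rostralmiddlefrontal,FP
rh_superiorfrontal,DMN
rh_superiorparietal,DAN
rh_superiortemporal,SOM
rh_supramarginal,VAN
rh_frontalpole,DMN
rh_temporalpole,LIM
rh_transversetemporal,SOM
rh_insula,VAN
lh_thalamus,SUB
lh_caudate,SUB
lh_putamen,SUB
lh_pallidum,SUB
lh_hippocampus,SUB
lh_amygdala,SUB
lh_accumbens,SUB
lh_ventraldc,SUB
rh_thalamus,SUB
rh_caudate,SUB
rh_putamen,SUB
rh_pallidum,SUB
rh_hippocampus,SUB
rh_amygdala,SUB
rh_accumbens,SUB
rh_ventraldc,SUB
lh_cerebellum,CER
rh_cerebellum,CER
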