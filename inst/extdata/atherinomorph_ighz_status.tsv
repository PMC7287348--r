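species	status
Gasterosteus_aculeatus	present
Oryzias_latipes	absent
Pachypanchax_playfairii	present
Callopanchax_toddi	present
Aphyosemion_australe	absent
Nothobranchius_furzeri	absent
Nothobranchius_orthonotus	absent
Kryptolebias_marmoratus	present
Austrofundulus_limnaeus	absent
Fundulus_heteroclitus	present
Cyprinodon_variegatus	present
Poecilia_reticulata	present
Poecilia_formosa	present
Xiphophorus_maculatus	present
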