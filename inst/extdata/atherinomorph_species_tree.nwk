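(Gasterosteus_aculeatus,(Oryzias_latipes,(((Pachypanchax_playfairii,(Callopanchax_toddi,(Aphyosemion_australe,(Nothobranchius_furzeri,Nothobranchius_orthonotus)))),(Kryptolebias_marmoratus,Austrofundulus_limnaeus)),(Fundulus_heteroclitus,(Cyprinodon_variegatus,(Poecilia_reticulata,(Poecilia_formosa,Xiphophorus_maculatus)))))));
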