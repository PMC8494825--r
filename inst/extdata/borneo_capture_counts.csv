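species,site,n_events
Sun bear,DVCA,15
Sun bear,LKWS,23
Sun bear,TWR,45
Banded civet,DVCA,195
Banded civet,LKWS,12
Banded civet,TWR,155
Binturong,DVCA,7
Binturong,TWR,2
Common palm civet,DVCA,78
Common palm civet,LKWS,85
Common palm civet,TWR,24
Malay civet,DVCA,346
Malay civet,LKWS,26
Malay civet,TWR,38
Bay cat,DVCA,1
Flat-headed cat,DVCA,3
Leopard cat,DVCA,16
Leopard cat,LKWS,5
Leopard cat,TWR,6
Marbled cat,DVCA,8
Marbled cat,TWR,2
Sunda clouded leopard,DVCA,2
Sunda clouded leopard,LKWS,1
Sunda clouded leopard,TWR,1
Sunda stink badger,DVCA,3
Sunda stink badger,LKWS,27
Sunda stink badger,TWR,1
Malay weasel,DVCA,1
Malay weasel,LKWS,1
Yellow-throated marten,DVCA,13
Yellow-throated marten,LKWS,1
Yellow-throated marten,TWR,2
Otter,DVCA,6
Banded linsang,DVCA,7
Banded linsang,LKWS,8
Banded linsang,TWR,10
Mongoose spp.,DVCA,54
Mongoose spp.,LKWS,29
Mongoose spp.,TWR,4
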