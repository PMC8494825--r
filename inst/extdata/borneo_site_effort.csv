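camera_id,site,operating_days
DVCA-all,DVCA,14134
LKWS-all,LKWS,18265
TWR-all,TWR,4980
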