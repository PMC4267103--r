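intervention,year,channel,coverage
itn,2010,facility,0
itn,2011,facility,0.5
antimalarials,2010,community,0
antimalarials,2011,community,0.5
pneumo_cm,2010,community,0
pneumo_cm,2011,community,0.5
ors_zinc,2010,community,0
ors_zinc,2011,community,0.5
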