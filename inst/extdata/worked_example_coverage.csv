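intervention,year,channel,coverage
vaccine,2010,facility,0
vaccine,2011,facility,0.5
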