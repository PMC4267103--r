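intervention,year,channel,coverage
treatment,2008,community,0.05
treatment,2008,facility,0.47
treatment,2013,community,0.15
treatment,2013,facility,0.33
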