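arm,uncontrolled,response,seizure_free,discontinued
tdm,9,19,26,24
non_tdm,10,10,4,18
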