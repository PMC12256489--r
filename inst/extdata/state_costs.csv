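arm,state,category,value
non_tdm,no_response,total,807.08
non_tdm,response,total,641.99
non_tdm,seizure_free,total,488.70
non_tdm,discontinue,total,787.31
non_tdm,no_response,hospitalization,101.26
non_tdm,response,hospitalization,151.22
non_tdm,seizure_free,hospitalization,99.36
non_tdm,discontinue,hospitalization,101.26
non_tdm,no_response,outpatient,100.22
non_tdm,response,outpatient,52.09
non_tdm,seizure_free,outpatient,55.75
non_tdm,discontinue,outpatient,100.22
non_tdm,no_response,per,172.76
non_tdm,response,per,189.98
non_tdm,seizure_free,per,171.05
non_tdm,no_response,other_asm,432.84
non_tdm,response,other_asm,248.70
non_tdm,seizure_free,other_asm,162.54
non_tdm,discontinue,other_asm,479.73
tdm,no_response,total,988.95
tdm,response,total,872.10
tdm,seizure_free,total,609.16
tdm,discontinue,total,787.31
tdm,no_response,hospitalization,420.14
tdm,response,hospitalization,384.48
tdm,seizure_free,hospitalization,179.96
tdm,discontinue,hospitalization,420.14
tdm,no_response,outpatient,135.13
tdm,response,outpatient,116.03
tdm,seizure_free,outpatient,84.66
tdm,discontinue,outpatient,135.13
tdm,no_response,per,164.80
tdm,response,per,187.35
tdm,seizure_free,per,189.92
tdm,no_response,other_asm,250.78
tdm,response,other_asm,166.15
tdm,seizure_free,other_asm,136.52
tdm,discontinue,other_asm,338.13
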