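arm,state,n_outpatient,n_low,n_high,consult_cost
tdm,seizure_free,3.83,NA,NA,10.82
tdm,response,4.97,1.66,8.28,12.06
tdm,no_response,6.40,0.72,13.52,9.83
tdm,discontinue,6.40,0.72,13.52,9.83
non_tdm,seizure_free,2.43,0.84,4.02,11.66
non_tdm,response,2.77,0.84,4.70,7.52
non_tdm,no_response,4.89,1.51,8.27,9.21
non_tdm,discontinue,4.89,1.51,8.27,9.21
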