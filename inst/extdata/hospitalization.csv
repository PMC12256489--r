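arm,state,p_hosp,n_hosp,days,daily_cost,total
tdm,seizure_free,0.431,1.09,1.75,219.40,179.96
tdm,response,0.475,1.63,2.95,295.95,384.48
tdm,no_response,0.475,1.18,3.60,206.05,420.14
non_tdm,seizure_free,0.200,1.00,3.48,142.76,99.36
non_tdm,response,0.231,1.00,6.48,101.46,151.22
non_tdm,no_response,0.167,1.00,3.44,173.15,101.26
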