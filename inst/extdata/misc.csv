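key,value,low,high
or,0.461,0.220,0.965
tdm_count,1.74,0.64,2.83
tdm_unit_cost,121.8,NA,NA
test_cost,24.90,NA,NA
exam_cost,22.55,NA,NA
discount_rate,0.05,NA,NA
inflation_rate,0.0148,NA,NA
exchange_rate_rmb_per_usd,6.73,NA,NA
wtp_per_capita_gdp,12814,NA,NA
wtp_three_gdp,38442,NA,NA
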