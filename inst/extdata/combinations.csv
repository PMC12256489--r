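arm,state,drug,prob,low,high
non_tdm,seizure_free,LTG,0.000,0.000,0.200
non_tdm,seizure_free,TPM,0.200,0.160,0.240
non_tdm,seizure_free,LEV,0.300,0.240,0.360
non_tdm,seizure_free,CLZ,0.200,0.160,0.240
non_tdm,seizure_free,ZNS,0.200,0.160,0.240
non_tdm,seizure_free,VPA,0.400,0.320,0.480
non_tdm,seizure_free,CBZ,0.200,0.160,0.240
non_tdm,seizure_free,NZP,0.100,0.080,0.120
non_tdm,seizure_free,OXC,0.100,0.080,0.120
non_tdm,seizure_free,LCS,0.000,0.000,0.200
non_tdm,seizure_free,CLB,0.000,0.000,0.200
non_tdm,seizure_free,VGB,0.000,0.000,0.200
non_tdm,seizure_free,PB,0.000,0.000,0.200
non_tdm,response,LTG,0.000,0.000,0.200
non_tdm,response,TPM,0.250,0.200,0.300
non_tdm,response,LEV,0.438,0.350,0.525
non_tdm,response,CLZ,0.438,0.350,0.525
non_tdm,response,ZNS,0.063,0.050,0.075
non_tdm,response,VPA,0.375,0.300,0.450
non_tdm,response,CBZ,0.188,0.150,0.225
non_tdm,response,NZP,0.188,0.150,0.225
non_tdm,response,OXC,0.000,0.000,0.200
non_tdm,response,LCS,0.063,0.050,0.075
non_tdm,response,CLB,0.000,0.000,0.200
non_tdm,response,VGB,0.063,0.050,0.075
non_tdm,response,PB,0.063,0.050,0.075
non_tdm,no_response,LTG,0.308,0.246,0.369
non_tdm,no_response,TPM,0.231,0.185,0.277
non_tdm,no_response,LEV,0.769,0.615,0.923
non_tdm,no_response,CLZ,0.308,0.246,0.369
non_tdm,no_response,ZNS,0.231,0.185,0.277
non_tdm,no_response,VPA,0.462,0.369,0.554
non_tdm,no_response,CBZ,0.077,0.062,0.092
non_tdm,no_response,NZP,0.077,0.062,0.092
non_tdm,no_response,OXC,0.077,0.062,0.092
non_tdm,no_response,LCS,0.000,0.000,0.200
non_tdm,no_response,CLB,0.077,0.062,0.092
non_tdm,no_response,VGB,0.000,0.000,0.200
non_tdm,no_response,PB,0.000,0.000,0.200
tdm,seizure_free,LTG,0.000,0.000,0.200
tdm,seizure_free,TPM,0.128,0.103,0.154
tdm,seizure_free,LEV,0.282,0.226,0.338
tdm,seizure_free,CLZ,0.026,0.021,0.031
tdm,seizure_free,ZNS,0.026,0.021,0.031
tdm,seizure_free,VPA,0.385,0.308,0.462
tdm,seizure_free,CBZ,0.000,0.000,0.200
tdm,seizure_free,NZP,0.077,0.062,0.092
tdm,seizure_free,OXC,0.231,0.185,0.277
tdm,seizure_free,LCS,0.000,0.000,0.200
tdm,seizure_free,CLB,0.000,0.000,0.200
tdm,seizure_free,VGB,0.000,0.000,0.200
tdm,seizure_free,PB,0.026,0.021,0.031
tdm,response,LTG,0.138,0.110,0.166
tdm,response,TPM,0.345,0.276,0.414
tdm,response,LEV,0.276,0.221,0.331
tdm,response,CLZ,0.103,0.083,0.124
tdm,response,ZNS,0.069,0.055,0.083
tdm,response,VPA,0.345,0.276,0.414
tdm,response,CBZ,0.069,0.055,0.083
tdm,response,NZP,0.207,0.166,0.248
tdm,response,OXC,0.103,0.083,0.124
tdm,response,LCS,0.034,0.028,0.041
tdm,response,CLB,0.000,0.000,0.200
tdm,response,VGB,0.034,0.028,0.041
tdm,response,PB,0.000,0.000,0.200
tdm,no_response,LTG,0.188,0.150,0.225
tdm,no_response,TPM,0.563,0.450,0.675
tdm,no_response,LEV,0.250,0.200,0.300
tdm,no_response,CLZ,0.063,0.050,0.075
tdm,no_response,ZNS,0.000,0.000,0.200
tdm,no_response,VPA,0.625,0.500,0.750
tdm,no_response,CBZ,0.000,0.000,0.200
tdm,no_response,NZP,0.250,0.200,0.300
tdm,no_response,OXC,0.125,0.100,0.150
tdm,no_response,LCS,0.000,0.000,0.200
tdm,no_response,CLB,0.063,0.050,0.075
tdm,no_response,VGB,0.063,0.050,0.075
tdm,no_response,PB,0.000,0.000,0.200
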