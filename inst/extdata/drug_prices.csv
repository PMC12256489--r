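drug,unit_price
CBZ,0.64
CLB,47.10
CLZ,36.85
LCS,19.53
LEV,1.88
LTG,8.50
OXC,1.84
PB,2.58
PER,335.81
TPM,7.61
VPA,0.71
VGB,5.50
NZP,4.99
ZNS,9.44
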