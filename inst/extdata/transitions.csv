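phase,from,to,prob
first,no_response,no_response,0.200
first,no_response,response,0.267
first,no_response,seizure_free,0.241
first,no_response,discontinue,0.292
subsequent,no_response,no_response,0.708
subsequent,no_response,response,0.042
subsequent,no_response,seizure_free,0.000
subsequent,no_response,discontinue,0.250
subsequent,response,no_response,0.031
subsequent,response,response,0.875
subsequent,response,seizure_free,0.063
subsequent,response,discontinue,0.031
subsequent,seizure_free,seizure_free,1.000
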