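state,utility,low,high
no_response,0.500,0.400,0.600
response,0.597,0.480,0.720
seizure_free,0.650,0.520,0.780
discontinue,0.500,0.400,0.600
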