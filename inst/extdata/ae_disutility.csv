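event,disutility,low,high
dizziness,0.0047,0.0037,0.0057
somnolence,0.0047,0.0037,0.0057
irritability,0.0047,0.0037,0.0057
ataxia,0.0047,0.0037,0.0057
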