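arm,event,prob,prob_low,prob_high,cost,cost_low,cost_high
non_tdm,dizziness,0.091,0.073,0.109,318.7,224.0,596.4
non_tdm,somnolence,0.076,0.061,0.091,318.7,224.0,596.4
non_tdm,irritability,0.106,0.085,0.127,318.7,224.0,596.4
non_tdm,ataxia,0.045,0.036,0.055,318.7,224.0,596.4
tdm,dizziness,0.048,0.038,0.057,318.7,224.0,596.4
tdm,somnolence,0.018,0.014,0.022,318.7,224.0,596.4
tdm,irritability,0.012,0.010,0.014,318.7,224.0,596.4
tdm,ataxia,0.012,0.010,0.014,318.7,224.0,596.4
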