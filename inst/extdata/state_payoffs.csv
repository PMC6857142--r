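state,utility,annual_cost_eur
mild,0.77,2600
moderate,0.60,7801
severe,0.47,20708
total,0.41,62407
dead,0.00,0
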