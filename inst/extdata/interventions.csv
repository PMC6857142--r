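intervention,participants,booster_unit_cost_eur
SM,171,19
PV,174,71
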