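from,mild,moderate,severe,total,dead
mild,0.79,0.13,0.03,0.02,0.03
moderate,0.08,0.82,0.03,0.01,0.06
severe,0.02,0.12,0.61,0.11,0.14
total,0.00,0.03,0.18,0.63,0.16
dead,0.00,0.00,0.00,0.00,1.00
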