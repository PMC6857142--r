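arm,n,mild,moderate,severe,total,dead
control,114,87,19,6,0,2
SM,171,149,11,3,3,5
PV,174,150,19,1,0,4
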