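intervention,item,amount_eur
SM,education,2143
SM,salaries,21071
SM,travel,234
SM,rooms,3222
SM,materials,623
PV,education,2143
PV,salaries,9322
PV,travel,238
PV,rooms,0
PV,materials,634
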