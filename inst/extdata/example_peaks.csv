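peak_id,polarity,neutral_mass,rt_min,S1,S2
cys,negative,121.01975,7,75000,80000
cys_m4,negative,125.026849,7.01,25000,26000
junk,negative,350.1,3.2,40000,NA
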