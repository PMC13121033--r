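name,mass_delta,mass_multiplier,polarity_scope
13C1,1.0033548350700006,1,any
13C2,2.006709670140001,1,any
34S,1.9957958999999974,1,any
18O,2.0042463804000015,1,any
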