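name,mass_delta,mass_multiplier,polarity_scope
Na-H,21.98194424883,1,any
K-H,37.95588164793,1,any
+NH3,17.02654910101,1,any
-H2O,-18.01056468374,1,any
+HCOOH,46.005479303339996,1,any
+HCl,35.97667771207,1,any
dimer,0,2,any
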