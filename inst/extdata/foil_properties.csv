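material,thermal_conductivity_W_mK,melting_point_C,density_g_cm3
Aluminum,167,582,2.7
Molybdenum,138,2620,10.2
Havar,13,1480,8.3
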