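symbol,Z,molar_mass_g_mol,mean_excitation_eV
H,1,1.008,19.2
C,6,12.011,78.0
N,7,14.007,82.0
O,8,15.999,95.0
Na,11,22.990,149.0
Al,13,26.982,166.0
Si,14,28.085,173.0
Cr,24,51.996,257.0
Mn,25,54.938,272.0
Fe,26,55.845,286.0
Co,27,58.933,297.0
Ni,28,58.693,311.0
Cu,29,63.546,322.0
Mo,42,95.95,424.0
Te,52,127.60,485.0
W,74,183.84,727.0
Pt,78,195.08,790.0
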