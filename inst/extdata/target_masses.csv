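thickness_mm,mass_mg
1.0,640.9
0.8,512.7
0.5,320.5
0.3,192.3
0.1,64.1
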