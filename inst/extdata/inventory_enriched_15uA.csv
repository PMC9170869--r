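symbol,half_life,unit,decay_modes,eob_MBq,eob_pct,after72h_MBq,after72h_pct,anomaly
I-118,13.7,min,ECB+:100,71.447,0.85,0,0,
I-119,19.1,min,ECB+:100,69.449,0.83,0,0,
I-120,81.6,min,ECB+:100,77.182,0.92,0,0,
I-121,2.12,h,ECB+:100,223.904,2.67,0,0,
I-122,3.6,min,ECB+:100,1732.821,20.69,0,0,
I-123,13.2,h,ECB+:100,1151.958,13.75,26.455,11.46,
I-124,4.2,d,ECB+:100,332.334,3.97,201.983,87.50,
N-13,9.9,min,ECB+:100,4972.319,59.36,0,0,
Sb-118,3.6,min,ECB+:100,72.187,0.86,0,0,
Sb-119,38.2,h,EC:100,1.924,0.02,0.518,0.23,
Te-118,6.0,d,EC:100,0.518,0.01,0.370,0.16,
Te-119,16.1,h,ECB+:100,4.514,0.05,0.185,0.09,after72h
Te-121,19.2,d,ECB+:100,1.480,0.02,1.332,0.57,
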