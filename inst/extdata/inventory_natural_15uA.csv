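symbol,half_life,unit,decay_modes,eob_MBq,eob_pct,after72h_MBq,after72h_pct,anomaly
He-6,806.7,ms,B-:100,71.817,0.86,0,0,
I-119,19.1,min,ECB+:100,69.079,0.82,0,0,
I-120,81.6,min,ECB+:100,38.406,0.46,0,0,
I-121,2.12,h,ECB+:100,111.370,1.33,0,0,
I-122,3.6,min,ECB+:100,1221.111,14.58,0,0,
I-123,13.2,h,ECB+:100,70.596,0.84,1.628,3.23,
I-124,4.2,d,ECB+:100,35.594,0.42,21.608,43.13,
I-125,59.4,d,EC:100,3.996,0.05,3.848,7.66,
I-126,12.9,d,ECB+:52.7;B-:47.3,17.316,0.21,14.726,29.38,
I-128,24.9,min,B-:93.1;ECB+:6.9,5404.738,64.52,0,0,
I-130,12.36,h,B-:100,361.527,4.32,6.364,12.72,
N-13,9.9,min,ECB+:100,5161.833,61.62,0,0,
O-14,70.6,s,ECB+:100,143.671,1.71,0,0,
Sb-119,38.2,h,EC:100,1.928,0.02,0.518,1.04,
Sb-122,2.7,d,B-:97.59;ECB+:2.41,1.147,0.01,0.518,1.05,after72h
Te-119,16.1,h,ECB+:100,4.514,0.05,0.185,0.40,after72h
Te-121,19.2,d,ECB+:100,0.666,0.01,0.592,1.16,after72h_pct
Te-127,9.4,h,B-:100,22.681,0.27,0.111,0.22,
Te-129,66.6,min,B-:100,42.513,0.51,0,0,
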