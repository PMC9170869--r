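symbol,half_life,unit,decay_modes,eob_MBq,eob_pct,after72h_MBq,after72h_pct,anomaly
He-6,806.7,ms,B-:100,72.483,1.24,0,0,
I-119,19.1,min,ECB+:100,138.010,2.36,0,0,
I-120,81.6,min,ECB+:100,76.664,1.31,0,0,
I-122,3.6,min,ECB+:100,717.393,12.27,0,0,
I-123,13.2,h,ECB+:100,672.623,11.51,15.429,10.38,
I-124,4.2,d,ECB+:100,214.711,3.67,130.499,87.71,
N-13,9.9,min,ECB+:100,3794.831,64.92,0,0,
O-14,70.6,s,ECB+:100,143.449,2.45,0,0,
Sb-119,38.2,h,EC:100,3.848,0.07,1.036,0.70,
Sb-122,2.7,d,B-:97.59;ECB+:2.41,1.147,0.02,0.518,0.35,after72h
Te-119,16.1,h,ECB+:100,8.991,0.15,0.407,0.27,
Te-121,19.2,d,ECB+:100,0.962,0.02,0.888,0.59,after72h
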