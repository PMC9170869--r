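symbol,half_life,unit,decay_modes,eob_MBq,eob_pct,after72h_MBq,after72h_pct,anomaly
Be-11,13.8,s,B-:100,72.483,0.87,0,0,
He-6,806.7,ms,B-:100,72.483,0.87,0,0,
I-120,81.6,min,ECB+:100,38.739,0.46,0,0,
I-122,3.6,min,ECB+:100,434.972,5.19,0,0,
I-123,13.2,h,ECB+:100,65.786,0.79,1.517,4.44,
I-124,4.2,d,ECB+:100,23.199,0.28,14.097,41.47,
I-125,59.4,d,EC:100,3.552,0.04,3.404,10.06,
I-126,12.9,d,ECB+:52.7;B-:47.3,14.319,0.17,12.173,35.84,
I-128,24.9,min,B-:93.1;ECB+:6.9,3326.115,39.71,0,0,
I-130,12.36,h,B-:100,157.916,1.89,2.775,8.19,
N-13,9.9,min,ECB+:100,3979.609,47.51,0,0,
O-14,70.6,s,ECB+:100,72.483,0.87,0,0,
O-15,122.2,s,ECB+:100,72.483,0.87,0,0,
Te-129,69.6,min,B-:100,42.92,0.51,0,0,
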