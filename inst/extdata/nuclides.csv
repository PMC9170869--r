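symbol,half_life,unit,decay_modes
He-6,806.7,ms,B-:100
Be-11,13.8,s,B-:100
N-13,9.965,min,ECB+:100
O-14,70.62,s,ECB+:100
O-15,122.24,s,ECB+:100
I-118,13.7,min,ECB+:100
I-119,19.1,min,ECB+:100
I-120,81.6,min,ECB+:100
I-121,2.12,h,ECB+:100
I-122,3.63,min,ECB+:100
I-123,13.2235,h,ECB+:100
I-124,4.176,d,ECB+:100
I-125,59.407,d,EC:100
I-126,12.93,d,ECB+:52.7;B-:47.3
I-128,24.99,min,B-:93.1;ECB+:6.9
I-130,12.36,h,B-:100
I-131,8.025,d,B-:100
Sb-118,3.6,min,ECB+:100
Sb-119,38.19,h,EC:100
Sb-122,2.7238,d,B-:97.59;ECB+:2.41
Te-118,6.00,d,EC:100
Te-119,16.05,h,ECB+:100
Te-121,19.17,d,ECB+:100
Te-127,9.35,h,B-:100
Te-129,69.6,min,B-:100
F-18,109.77,min,ECB+:100
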