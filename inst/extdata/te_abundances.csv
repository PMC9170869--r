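isotope,abundance_pct
Te-120,0.09
Te-122,2.55
Te-123,0.89
Te-124,4.74
Te-125,7.07
Te-126,18.84
Te-128,31.74
Te-130,34.08
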