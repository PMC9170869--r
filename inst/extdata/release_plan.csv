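target,current_uA,time_h,i124_MBq,i124_pct,i123_MBq,i123_pct,consistent
natural,10,127,9.62,40.23,0.74,0.35,FALSE
natural,15,122,15.318,45.25,0.111,0.35,TRUE
enriched,10,149,76.627,98.01,0.259,0.35,TRUE
enriched,15,151,117.327,98.34,0.407,0.35,TRUE
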