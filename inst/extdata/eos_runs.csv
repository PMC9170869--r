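run,current_uA,time_h,eos_experiment_MBq,eos_simulated_MBq,difference_pct
1,10,73.88,20.72,33.30,60.71
2,10,118.14,13.69,24.79,81.08
3,10,122.77,14.43,24.42,69.23
4,10,96.50,18.50,28.12,52.00
5,10,131.36,15.91,23.68,48.83
6,10,72.39,20.72,34.04,64.28
7,10,70.44,25.16,34.41,36.76
8,10,70.89,23.31,34.41,47.62
9,10,144.87,14.43,22.20,53.85
10,15,71.49,56.61,50.32,11.11
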