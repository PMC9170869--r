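run,current_uA,activity_product_MBq,activity_waste_MBq,activity_total_MBq,product_pct,waste_pct
1,10,16.28,4.44,20.72,78.44,21.56
2,10,10.36,3.70,14.06,74.12,25.88
3,10,13.69,1.11,14.80,93.37,6.63
4,10,17.76,0.74,18.50,95.93,4.07
5,10,11.84,4.07,15.91,74.33,25.67
6,10,17.39,3.33,20.72,83.25,16.75
7,10,24.42,0.74,25.16,97.19,2.81
8,10,22.20,1.11,23.31,94.79,5.21
9,10,12.95,1.48,14.43,90.83,9.17
10,15,52.17,4.07,56.61,92.59,7.41
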