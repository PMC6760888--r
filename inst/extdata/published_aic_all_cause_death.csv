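threshold,hr,ci_low,ci_high,aic,delta_aic_printed
0.75,1.31,1.19,1.43,33897.279,13.703
0.79,1.35,1.23,1.49,33888.656,5.080
0.80,1.37,1.24,1.50,33886.078,2.502
0.84,1.39,1.26,1.52,33883.576,0
0.89,1.39,1.26,1.54,33886.895,3.319
0.90,1.36,1.23,1.51,33893.001,9.425
0.95,1.24,1.10,1.40,33915.741,32.165
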