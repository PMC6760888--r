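threshold,hr,ci_low,ci_high,aic,delta_aic_printed
0.40,1.15,0.96,1.37,12623.098,5.471
0.45,1.20,1.01,1.42,12621.167,3.540
0.47,1.23,1.04,1.45,12619.995,2.368
0.70,1.15,0.99,1.35,12622.171,4.544
0.75,1.19,1.02,1.38,12620.743,3.116
0.78,1.24,1.06,1.44,12618.126,0.499
0.79,1.25,1.07,1.45,12617.627,0
0.80,1.24,1.06,1.45,12618.005,0.378
0.85,1.21,1.03,1.41,12619.881,2.254
0.87,1.15,0.98,1.35,12622.321,4.694
0.90,1.12,0.95,1.32,12623.467,5.840
0.95,1.04,0.86,1.26,12625.273,7.646
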