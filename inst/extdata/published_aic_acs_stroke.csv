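threshold,hr,ci_low,ci_high,aic,delta_aic_printed
0.45,1.65,1.51,1.81,41831.956,16.854
0.50,1.65,1.51,1.81,41826.994,11.892
0.51,1.67,1.53,1.82,41821.344,6.242
0.52,1.69,1.54,1.84,41815.102,0
0.54,1.67,1.53,1.83,41818.118,3.016
0.55,1.65,1.51,1.80,41824.783,9.681
0.65,1.61,1.47,1.75,41831.060,15.958
0.70,1.52,1.39,1.66,41854.867,39.765
0.80,1.41,1.29,1.54,41883.776,68.674
0.95,1.11,1.00,1.24,41939.465,124.363
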