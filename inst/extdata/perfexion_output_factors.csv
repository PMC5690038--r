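collimator,row,calculated,manufacturer
4,1,0.811,0.812
4,2,0.826,0.823
4,3,0.791,0.795
4,4,0.731,0.726
4,5,0.664,0.664
4,total,0.814,0.814
4,calc,0.809,0.814
8,1,0.939,0.934
8,2,0.920,0.919
8,3,0.875,0.874
8,4,0.784,0.782
8,5,0.706,0.708
8,total,0.901,0.900
8,calc,0.894,0.900
16,1,0.961,0.961
16,2,1.000,1.000
16,3,0.980,0.981
16,4,0.917,0.914
16,5,0.849,0.847
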