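sample_id,cd_add,cd_add_solution,cd_dgt,ca,mg,h
S-1,0,0.0,0.0,0.0125,0.00863,0.0000224
S-1,15,0.29,0.031,0.0125,0.00982,0.0000283
S-1,150,2.9,12,0.0629,0.0491,0.000356
S-1,1000,19,730,0.249,0.179,0.00126
A-1,0,0.00,0.00,0.00691,0.0103,0.100
A-1,15,0.071,0.38,0.00704,0.0107,0.178
A-1,150,0.71,9.4,0.0125,0.0168,0.283
A-1,1000,4.7,210,0.0274,0.0256,0.502
B-1,0,0.00,0.00,0.0599,0.0741,0.0448
B-1,15,0.14,1.0,0.0724,0.103,0.0564
B-1,150,1.4,31,0.210,0.288,0.142
B-1,1000,9.2,480,0.414,0.535,0.200
C-1,0,0.00,0.00,0.773,0.272,0.000893
C-1,15,0.12,0.043,0.724,0.272,0.00159
C-1,150,1.2,1.5,1.92,0.428,0.00178
C-1,1000,8.3,110,11.0,2.14,0.0252
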