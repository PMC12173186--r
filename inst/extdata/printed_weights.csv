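indicator,dimension,dimension_weight,within_weight
I_1,resource,0.153,0.281
I_2,resource,0.153,0.379
I_3,resource,0.153,0.340
I_4,functional,0.218,0.562
I_5,functional,0.218,0.401
I_6,functional,0.218,0.038
I_7,performance,0.289,0.152
I_8,performance,0.289,0.588
I_9,performance,0.289,0.261
I_10,learning,0.210,0.721
I_11,learning,0.210,0.279
I_12,internet,0.130,0.330
I_13,internet,0.130,0.580
I_14,internet,0.130,0.091
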