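id,ic50_uM,pic50,role
1,17.000,4.770,train
2,0.970,6.013,test
3,0.005,8.301,train
4,,2.620,train
5,61.000,4.215,train
6,1.500,5.824,train
7,0.008,8.097,test
8,0.010,8.000,train
9,0.003,8.523,train
10,0.019,7.721,test
11,0.017,7.770,train
12,21.000,4.678,test
13,0.830,6.081,train
14,6.400,5.194,test
15,8.900,5.051,train
16,0.220,6.658,train
17,0.019,7.721,train
18,0.024,7.620,train
19,0.039,7.409,train
20,0.052,7.284,test
21,0.044,7.357,train
22,0.580,6.237,train
23,1.400,5.854,train
24,6.700,5.174,train
25,44.700,4.350,train
26,30.300,4.519,test
27,27.700,4.558,train
28,,4.046,train
29,17.000,4.770,train
30,18.200,4.740,train
31,,3.983,train
32,23.500,4.629,train
33,39.800,4.400,train
34,8.700,5.061,train
35,0.510,6.292,train
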