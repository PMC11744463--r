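age,sex,qx
40,F,0.000717
41,F,0.000788
42,F,0.000865
43,F,0.000951
44,F,0.001044
45,F,0.001147
46,F,0.00126
47,F,0.001384
48,F,0.00152
49,F,0.00167
50,F,0.001835
51,F,0.002015
52,F,0.002214
53,F,0.002432
54,F,0.002671
55,F,0.002934
56,F,0.003222
57,F,0.003539
58,F,0.003888
59,F,0.00427
60,F,0.00469
61,F,0.005151
62,F,0.005657
63,F,0.006213
64,F,0.006823
65,F,0.007493
66,F,0.008229
67,F,0.009036
68,F,0.009922
69,F,0.010895
70,F,0.011962
71,F,0.013133
72,F,0.014418
73,F,0.015828
74,F,0.017375
75,F,0.019071
76,F,0.02093
77,F,0.022969
78,F,0.025204
79,F,0.027654
80,F,0.030338
81,F,0.033277
82,F,0.036497
83,F,0.040021
84,F,0.043878
85,F,0.048097
86,F,0.05271
87,F,0.057752
88,F,0.06326
89,F,0.069274
90,F,0.075837
91,F,0.082992
92,F,0.090789
93,F,0.099279
94,F,0.108513
95,F,0.118549
96,F,0.129444
97,F,0.141257
98,F,0.154049
99,F,0.167884
100,F,0.182821
40,M,0.001206
41,M,0.001322
42,M,0.001449
43,M,0.001589
44,M,0.001742
45,M,0.001909
46,M,0.002093
47,M,0.002295
48,M,0.002516
49,M,0.002758
50,M,0.003023
51,M,0.003314
52,M,0.003633
53,M,0.003982
54,M,0.004365
55,M,0.004784
56,M,0.005244
57,M,0.005748
58,M,0.0063
59,M,0.006905
60,M,0.007568
61,M,0.008295
62,M,0.00909
63,M,0.009962
64,M,0.010916
65,M,0.011962
66,M,0.013107
67,M,0.014361
68,M,0.015734
69,M,0.017237
70,M,0.018883
71,M,0.020683
72,M,0.022654
73,M,0.024809
74,M,0.027167
75,M,0.029746
76,M,0.032565
77,M,0.035647
78,M,0.039014
79,M,0.042692
80,M,0.046709
81,M,0.051093
82,M,0.055876
83,M,0.061093
84,M,0.06678
85,M,0.072974
86,M,0.079719
87,M,0.087057
88,M,0.095035
89,M,0.103701
90,M,0.113108
91,M,0.123307
92,M,0.134355
93,M,0.146307
94,M,0.159221
95,M,0.173156
96,M,0.188168
97,M,0.204314
98,M,0.221646
99,M,0.240216
100,M,0.260066
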