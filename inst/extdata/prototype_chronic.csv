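hr_bpm,count
85,1982
70,1938
75,1938
80,1934
90,1659
90.5,1534
85.5,1498
89.5,1484
70.5,1473
84.5,1472
95,1449
95.5,1419
80.5,1174
94.5,1171
100,1162
91,1161
96,1140
100.5,1122
86,1101
99.5,1086
75.5,1080
89,1065
91.5,1029
79.5,2524
74.5,2496
76,2427
81,2426
74,2184
69.5,2161
71,2124
84,2094
79,2084
86.5,2073
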