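hr_bpm,count
95,1993
85,1921
80,1407
75,1392
75.5,1316
85.5,1288
74.5,1215
80.5,1202
95.5,1160
84.5,1119
100,1087
90,2999
100.5,2997
90.5,2279
79.5,2219
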