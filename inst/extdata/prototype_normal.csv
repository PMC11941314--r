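hr_bpm,count
90,1858
85,1858
65,1814
90.5,1792
85.5,1792
70,1780
70.5,1484
60,1354
55,1331
69.5,1216
60.5,1203
89.5,2023
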