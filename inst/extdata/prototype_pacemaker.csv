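hr_bpm,count
75,1539
65,1536
70,1120
60,1115
65.5,2412
60.5,2397
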