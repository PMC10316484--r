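5,30,3,10,10,10,,,,,,
synthetic example (3 sites x 10 samples, 5 loci),,,S01,S02,S03,,,,,,
Sample,Pop,L01,,L02,,L03,,L04,,L05,
S01_001,S01,204,204,304,304,234,242,148,158,248,260
S01_002,S01,204,204,304,304,234,242,148,158,248,260
S01_003,S01,204,210,304,310,234,240,148,148,248,250
S01_004,S01,204,204,304,314,242,242,158,158,252,260
S01_005,S01,204,204,302,304,242,242,148,148,248,250
S01_006,S01,204,210,304,310,234,240,148,148,248,250
S01_007,S01,204,204,304,304,234,242,148,158,248,260
S01_008,S01,204,204,304,304,234,242,148,160,250,260
S01_009,S01,204,210,304,304,234,240,148,148,248,252
S01_010,S01,204,210,304,304,234,240,148,148,248,252
S02_001,S02,204,206,310,314,234,236,154,154,250,250
S02_002,S02,204,210,314,314,232,232,150,150,260,260
S02_003,S02,206,206,314,314,232,242,154,158,250,254
S02_004,S02,206,206,314,314,232,242,154,158,250,254
S02_005,S02,200,210,314,314,232,232,148,162,248,256
S02_006,S02,200,210,314,314,232,232,148,162,248,256
S02_007,S02,204,206,302,302,234,242,148,154,250,250
S02_008,S02,206,206,302,314,232,234,150,154,250,260
S02_009,S02,206,206,302,314,232,234,150,154,250,260
S02_010,S02,204,204,304,314,232,236,154,154,250,260
S03_001,S03,210,210,310,310,234,234,148,150,252,258
S03_002,S03,210,210,310,310,234,234,148,150,252,258
S03_003,S03,210,210,310,310,234,234,148,150,252,258
S03_004,S03,210,210,300,310,234,234,148,150,254,258
S03_005,S03,202,210,300,310,234,242,150,150,258,258
S03_006,S03,210,210,310,310,234,234,148,150,252,258
S03_007,S03,210,210,300,310,234,234,148,150,254,258
S03_008,S03,196,210,310,312,234,240,148,150,248,258
S03_009,S03,210,210,310,310,234,234,148,150,252,258
S03_010,S03,0,0,310,312,234,240,148,150,248,258
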