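subject,sample_size,top1,top2,top3,precision,recall
1,585,0.701,0.863,0.923,0.711,0.701
2,666,0.679,0.821,0.910,0.677,0.679
3,389,0.590,0.846,0.897,0.585,0.590
4,415,0.639,0.831,0.891,0.653,0.639
5,241,0.551,0.694,0.776,0.575,0.551
6,549,0.718,0.873,0.918,0.710,0.718
7,553,0.667,0.874,0.919,0.649,0.667
8,515,0.689,0.826,0.922,0.733,0.689
9,609,0.598,0.844,0.943,0.589,0.598
10,536,0.722,0.861,0.926,0.748,0.722
11,509,0.706,0.853,0.912,0.738,0.706
12,523,0.714,0.886,0.933,0.742,0.714
13,222,0.622,0.733,0.844,0.579,0.622
14,234,0.702,0.894,0.936,0.719,0.702
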