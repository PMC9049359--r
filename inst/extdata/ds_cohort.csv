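subject,classif_time_s,acc_online,acc_offline,itr_bits_min
1,1.3,0.77,0.89,50.95
2,1.3,0.91,1.00,81.91
3,0.7,0.91,1.00,166.30
4,1.4,0.91,0.97,74.66
5,1.0,0.94,0.96,116.56
6,1.3,0.94,0.95,88.71
7,1.9,0.80,0.89,38.76
8,2.8,0.75,0.79,22.78
9,1.9,0.88,0.97,51.50
10,2.1,0.66,0.75,21.61
11,0.7,0.92,1.00,150.26
12,0.8,0.86,1.00,108.58
13,0.9,0.86,0.93,103.91
14,1.2,0.79,0.95,59.45
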