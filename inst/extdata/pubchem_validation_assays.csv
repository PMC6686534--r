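aid,compounds_tested,actives,pct_actives_printed
522,64907,1225,1.89
527,24074,64,0.27
555,65239,316,0.48
560,64907,979,1.51
746,59787,366,0.61
798,218716,302,0.14
1006,195564,2976,1.52
1273,127297,1153,0.91
1515,217964,445,0.20
2129,315002,2199,0.70
2280,324750,1419,0.44
2540,330397,4119,1.25
2544,330397,393,0.12
2553,305614,3253,1.06
2606,324751,157,0.05
463104,331676,1100,0.33
504406,323914,194,0.06
504454,339285,1446,0.43
588497,340322,780,0.23
602363,347157,446,0.13
623901,332759,470,0.14
624414,400339,482,0.12
686964,369939,1149,0.31
720700,369939,3123,0.84
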