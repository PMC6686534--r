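aid,compounds_tested,actives,pct_actives_printed
834,84880,123,0.14
1236,218607,799,0.37
1510,217964,569,0.26
1899,302667,998,0.33
2732,218659,8240,3.77
463165,305614,1365,0.45
588621,359231,887,0.25
602229,362013,1281,0.35
720543,369939,2005,0.54
1117267,91911,1155,1.26
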