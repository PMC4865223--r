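chromosome,snps,length_cM,biggest_gap_cM,unique_positions
1A,231,175.5,18.2,90
1B,298,181.4,11.9,121
2A,403,218.3,12.6,132
2B,324,234.9,13,141
3A,204,199.6,13.6,97
3B,337,229.7,14.2,142
4A,231,229.3,21.1,115
4B,281,163.7,18.8,100
5A,279,288.2,15.5,134
5B,280,246.4,12.1,134
6A,172,178.2,11.1,96
6B,253,183.4,20.8,114
7A,292,237.6,12.2,135
7B,144,197.3,20.9,73
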