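element	nominal	mass	abundance
H	1	1.00782503207	0.999885
H	2	2.01410177785	0.000115
C	12	12.0	0.9893
C	13	13.00335483507	0.0107
N	14	14.0030740048	0.99636
N	15	15.0001088989	0.00364
O	16	15.9949146196	0.99757
O	17	16.9991317565	0.00038
O	18	17.9991596129	0.00205
P	31	30.97376163	1.0
S	32	31.9720710015	0.9499
S	33	32.9714587600	0.0075
S	34	33.9678669000	0.0425
S	36	35.9670807600	0.0001
D	2	2.01410177785	1.0
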