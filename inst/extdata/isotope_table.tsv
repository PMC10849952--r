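element	nominal	mass	abundance
H	1	1.0078250319	0.999885
H	2	2.0141017781	0.000115
D	2	2.0141017781	1.0
C	12	12.0	0.9893
C	13	13.0033548351	0.0107
N	14	14.0030740052	0.99636
N	15	15.0001088989	0.00364
O	16	15.9949146221	0.99757
O	17	16.9991315	0.00038
O	18	17.9991604	0.00205
S	32	31.97207069	0.9499
S	33	32.9714585	0.0075
S	34	33.96786683	0.0425
S	36	35.96708088	0.0001
Cl	35	34.96885271	0.7576
Cl	37	36.9659026	0.2424
Na	23	22.9897692809	1.0
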