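carbons	double_bonds	series
16	1	n-7
17	1	n-7
18	1	n-9
20	1	n-9
22	1	n-9
24	1	n-9
26	1	n-9
18	2	n-6
18	3	n-3
18	4	n-3
20	2	n-6
20	3	n-6
20	4	n-6
20	5	n-3
22	2	n-6
22	4	n-6
22	5	n-3
22	6	n-3
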