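case	step	quantity	T150	T200	T300
(120)BC	dept	dG_act	25.0	25.9	28.2
(120)BC	dept	dG_rxn	-51.1	-50.7	-49.7
(120)BC	dept	k	1.4e5	5.9e6	3.6e8
(120)BC	dept	t_half	1.4e-9	3.3e-11	5.3e-13
(120)BC	CC	dG_act	90.4	91.9	95.8
(120)BC	CC	dG_rxn	26.6	28.0	31.5
(120)BC	CC	k	3.5e-19	1.3e-11	4.3e-4
(120)BC	CC	t_half	5.5e14	1.5e7	0.45
(101)AB	CC	dG_act	74.7	75.0	76.1
(101)AB	CC	dG_rxn	65.7	66.1	67.3
(101)AB	CC	k	3.7e-14	7.8e-8	0.13
(101)AB	CC	t_half	5.2e9	2.5e3	1.4e-3
(101)BC	CC	dG_act	52.6	52.8	53.6
(101)BC	CC	dG_rxn	-53.9	-52.5	-48.8
(101)BC	CC	k	1.8e-6	8.1e-2	3.4e3
(101)BC	CC	t_half	1.1e2	2.4e-3	5.7e-8
(111)BC	CC	dG_act	174.3	175.1	177.5
(111)BC	CC	dG_rxn	156.1	156.5	157.9
(111)BC	CC	k	0	0	7.9e-17
(111)BC	CC	t_half	inf	inf	2.5e12
(111)BD	CC	dG_act	123.9	124.8	126.8
(111)BD	CC	dG_rxn	94.4	95.5	98.1
(111)BD	CC	k	0	0	4.3e-10
(111)BD	CC	t_half	inf	inf	4.5e5
(111)DE	CC	dG_act	143.0	143.4	144.5
(111)DE	CC	dG_rxn	144.8	145.1	146.1
(111)DE	CC	k	0	0	6.7e-11
(111)DE	CC	t_half	inf	inf	2.9e6
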