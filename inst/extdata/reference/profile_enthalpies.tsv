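case	step	dH0_act	dH0_rxn
gas	CC	311.3	39.1
(120)BC	dept	23.3	-52.2
(120)BC	CC	88.3	24.9
(101)AB	CC	74.7	65.9
(101)BC	CC	53.2	-55.5
(111)DE	CC	142.8	144.6
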