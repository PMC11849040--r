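case	complex	BE
(120)BC	R_dept	-163.7
(120)BC	R_CC	-192.9
(120)BC	IAN	-160.2
(101)AB	R_CC	-426.8
(101)AB	IAN_anion	-333.0
(101)BC	R_CC	-348.4
(101)BC	IAN_anion	-364.7
(111)BC	R_CC	-426.7
(111)BC	IAN_anion	-238.8
(111)BD	R_CC	-383.4
(111)BD	IAN_anion	-276.2
(111)DE	R_CC	-364.6
(111)DE	IAN_anion	-222.0
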