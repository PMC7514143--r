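	Advice	Effect	Mechanism	Int	Negative
Advice	178	5	3	2	33
Effect	2	269	9	0	80
Mechanism	7	4	232	0	59
Int	0	36	2	43	15
Negative	34	58	45	5	4595
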