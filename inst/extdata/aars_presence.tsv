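organism	alaS	argS	asnS	aspS	cysS	glnS	gltX	glyS	hisS	ileS	leuS	lysS	metG	pheS	proS	serS	thrS	trpS	tyrS	valS
Hodgkinia	1	0	0	0	0	0	1	1	1	1	0	0	1	1	1	0	0	1	0	1
Sulcia	1	0	1	0	0	1	1	1	0	1	1	1	1	1	1	1	0	1	1	1
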