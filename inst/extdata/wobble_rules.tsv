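anticodon34	modification	reads
G	none	C,T
C	none	G
A	none	T
T	none	A,G
T	xm5s2U	A,G
T	superwobble	A,C,G,T
C	lysidine	A
A	inosine	T,C,A
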