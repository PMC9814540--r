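resid	atom	donor	acceptor
*	N	1	0
*	O	0	1
*	OXT	0	1
SER	OG	1	1
THR	OG1	1	1
TYR	OH	1	1
CYS	SG	1	0
MET	SD	0	1
ASN	OD1	0	1
ASN	ND2	1	0
GLN	OE1	0	1
GLN	NE2	1	0
ASP	OD1	0	1
ASP	OD2	0	1
GLU	OE1	0	1
GLU	OE2	0	1
LYS	NZ	1	0
ARG	NE	1	0
ARG	NH1	1	0
ARG	NH2	1	0
HIS	ND1	0	1
HIS	NE2	1	0
TRP	NE1	1	0
PRO	N	0	0
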