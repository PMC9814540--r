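resid	atom	charge
*	N	-0.4157
*	H	0.2719
*	HN	0.2719
*	CA	0.0337
*	HA	0.0823
*	C	0.5973
*	O	-0.5679
*	OXT	-0.8055
SER	OG	-0.6546
SER	HG	0.4275
THR	OG1	-0.6761
THR	HG1	0.4102
TYR	OH	-0.5579
TYR	HH	0.3992
CYS	SG	-0.3119
CYS	HG	0.1933
MET	SD	-0.2737
ASN	OD1	-0.5931
ASN	ND2	-0.9191
ASN	HD21	0.4196
ASN	HD22	0.4196
GLN	OE1	-0.6086
GLN	NE2	-0.9407
GLN	HE21	0.4251
GLN	HE22	0.4251
ASP	CG	0.7994
ASP	OD1	-0.8014
ASP	OD2	-0.8014
GLU	CD	0.8054
GLU	OE1	-0.8188
GLU	OE2	-0.8188
LYS	NZ	-0.3854
LYS	HZ1	0.34
LYS	HZ2	0.34
LYS	HZ3	0.34
ARG	NE	-0.5295
ARG	HE	0.3456
ARG	CZ	0.8076
ARG	NH1	-0.8627
ARG	NH2	-0.8627
ARG	HH11	0.4478
ARG	HH12	0.4478
ARG	HH21	0.4478
ARG	HH22	0.4478
HIS	ND1	-0.5732
HIS	NE2	-0.2795
HIS	HE2	0.3339
HIS	HD1	0.3866
TRP	NE1	-0.3418
TRP	HE1	0.3412
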