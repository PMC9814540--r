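element	sigma	epsilon	charge
H	0.6000	0.0157	0.06
C	1.9080	0.1094	0.00
N	1.8240	0.1700	-0.40
O	1.6612	0.2100	-0.50
S	2.0000	0.2500	-0.10
P	2.1000	0.2000	0.80
F	1.7500	0.0610	-0.20
CL	1.9480	0.2650	-0.10
BR	2.2200	0.3200	-0.10
I	2.3500	0.4000	-0.05
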