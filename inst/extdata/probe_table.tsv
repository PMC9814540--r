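name	sigma_p	eps_p	charge	w_elst	w_steric	w_hphob	w_acc	w_don
C1=	1.908	0.086	0.00	0	1	0.7	0	0.2
OH2	1.600	0.012	0.00	0	1	0	1	1
CRY	1.800	0.100	0.00	0	1	0.5	0.5	0.5
I	2.350	0.400	0.00	0	1	0.8	0	0
O-	1.661	0.210	-1.00	1	1	0	0	1
DRY	1.908	0.109	0.00	0	1	1	0	0
N+	1.875	0.170	1.00	1	1	0	1	0
H	0.600	0.016	0.00	0	1	0	1	0
F3	1.750	0.061	0.00	0	1	0.4	0	0.1
OC2	1.661	0.210	0.00	0	1	0	0	1
I-H	2.200	0.300	0.00	0	1	0.3	0.6	0
NA+	1.868	0.003	1.00	1	1	0	0	1
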