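unit	position	gene
P_MBH	1	hoxK
P_MBH	2	hoxG
P_MBH	3	hoxZ
P_MBH	4	hoxM
P_MBH	5	hoxL
P_MBH	6	hoxO
P_MBH	7	hoxQ
P_MBH	8	hoxR
P_MBH	9	hoxT
P_MBH	10	hoxV
P_hyp	1	hypA1
P_hyp	2	hypB1
P_hyp	3	hypF1
P_hyp	4	hypC1
P_hyp	5	hypD1
P_hyp	6	hypE1
P_hyp	7	hypX
P_hyp	8	hoxA
P_RH	1	hoxB
P_RH	2	hoxC
P_RH	3	hoxJ
P_SH	1	hoxF
P_SH	2	hoxU
P_SH	3	hoxY
P_SH	4	hoxH
P_SH	5	hoxI
P_SH	6	hypA2
P_SH	7	hypB2
P_SH	8	hypF2
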