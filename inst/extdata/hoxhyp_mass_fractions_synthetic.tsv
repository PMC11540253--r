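gene	psi_percent
hoxK	0.02
hoxG	0.08
hoxZ	0.03
hoxM	0.02
hoxL	0.03
hoxO	0.02
hoxQ	0.02
hoxR	0.01
hoxT	0.02
hoxV	0.03
hypA1	0.05
hypB1	0.10
hypF1	0.12
hypC1	0.06
hypD1	0.10
hypE1	0.08
hypX	0.09
hoxA	0.06
hoxB	0.02
hoxC	0.03
hoxJ	0.02
hoxF	0.35
hoxU	0.25
hoxY	0.20
hoxH	0.55
hoxI	0.15
hypA2	0.03
hypB2	0.04
hypF2	0.03
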