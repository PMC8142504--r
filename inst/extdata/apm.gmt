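APM	antigen processing and presentation machinery	HLA-A	HLA-B	HLA-C	TAP1	TAP2	TAPBP	ERAP1	ERAP2	CANX	CALR	B2M	PDIA3	PSMB5	PSMB6	PSMB7	PSMB8	PSMB9	PSMB10
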