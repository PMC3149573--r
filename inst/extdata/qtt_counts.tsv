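trait	FATB	GONA	AHYP	THYG	HYPO
glucose	108	191	123	191	115
hydroxybutyrate	103	344	113	279	209
NEFA	458	1113	1919	655	1003
cholesterol	56	51	83	93	72
HDL_C	291	100	460	373	547
LDL_C	84	62	82	62	45
triglyceride	185	117	273	304	318
total_protein	207	63	89	80	95
ALT	166	613	112	3322	441
ALP	138	175	202	96	57
haptoglobin	84	45	70	118	72
PigMAP	51	254	100	99	58
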