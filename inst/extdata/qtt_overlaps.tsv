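trait	tissueA	tissueB	observed
HDL_C	FATB	THYG	17
HDL_C	AHYP	THYG	25
HDL_C	AHYP	HYPO	40
HDL_C	THYG	HYPO	50
NEFA	GONA	AHYP	211
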