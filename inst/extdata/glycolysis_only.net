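# glucose split into two pyruvate halves (C1-C2-C3 inverted, C4-C5-C6 direct)
METABOLITE	glc.x	6	source
METABOLITE	pyr	3	balanced
METABOLITE	pyr.x	3	sink
REACTION	GLYC	irr	glc.x (abcdef) -> pyr (cba) + pyr (def)
REACTION	PYROUT	irr	pyr (abc) -> pyr.x (abc)
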