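# reduced glycolysis + TCA + glutaminolysis network for recovery studies
METABOLITE	glc.x	6	source
METABOLITE	gln.x	5	source
METABOLITE	co2	1	source
METABOLITE	lac.x	3	sink
METABOLITE	glu.x	5	sink
METABOLITE	asp.x	4	sink
METABOLITE	pyr	3	balanced
METABOLITE	accoa	2	balanced
METABOLITE	cit	6	balanced
METABOLITE	akg	5	balanced
METABOLITE	mal	4	balanced
METABOLITE	oaa	4	balanced
METABOLITE	glu	5	balanced
REACTION	GLYC	irr	glc.x (abcdef) -> pyr (cba) + pyr (def)
REACTION	LDH	irr	pyr (abc) -> lac.x (abc)
REACTION	PDH	irr	pyr (abc) -> accoa (bc) + co2 (a)
REACTION	PC	irr	pyr (abc) + co2 (d) -> oaa (abcd)
REACTION	CS	irr	accoa (ab) + oaa (cdef) -> cit (abcdef)
REACTION	IDH	rev	cit (abcdef) -> akg (abcde) + co2 (f)
REACTION	AKGDH	irr	akg (abcde) -> mal (bcde) + co2 (a)
MAP2	akg (abcde) -> mal (edcb) + co2 (a)
REACTION	MDH	rev	mal (abcd) -> oaa (abcd)
REACTION	GLNUP	irr	gln.x (abcde) -> glu (abcde)
REACTION	GDH	irr	glu (abcde) -> akg (abcde)
REACTION	GLUOUT	irr	glu (abcde) -> glu.x (abcde)
REACTION	ASPOUT	irr	oaa (abcd) -> asp.x (abcd)
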