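# single-pass oxidative TCA scheme: glutamine -> glutamate -> aKG -> ... -> OAA; OAA + unlabeled AcCoA -> citrate
METABOLITE	gln.x	5	source
METABOLITE	accoa.x	2	source
METABOLITE	co2	1	source
METABOLITE	cit.x	6	sink
METABOLITE	asp.x	4	sink
METABOLITE	glu	5	balanced
METABOLITE	akg	5	balanced
METABOLITE	suc	4	balanced
METABOLITE	mal	4	balanced
METABOLITE	oaa	4	balanced
METABOLITE	cit	6	balanced
METABOLITE	asp	4	balanced
REACTION	GLS	irr	gln.x (abcde) -> glu (abcde)
REACTION	GDH	irr	glu (abcde) -> akg (abcde)
REACTION	AKGDH	irr	akg (abcde) -> suc (bcde) + co2 (a)
REACTION	SDH	irr	suc (abcd) -> mal (abcd)
MAP2	suc (abcd) -> mal (dcba)
REACTION	MDH	irr	mal (abcd) -> oaa (abcd)
REACTION	CS	irr	accoa.x (ab) + oaa (cdef) -> cit (abcdef)
REACTION	CITOUT	irr	cit (abcdef) -> cit.x (abcdef)
REACTION	AST	irr	oaa (abcd) -> asp (abcd)
REACTION	ASPOUT	irr	asp (abcd) -> asp.x (abcd)
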