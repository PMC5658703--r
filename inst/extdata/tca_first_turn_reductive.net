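# single-pass reductive carboxylation scheme: glutamine-derived aKG + unlabeled CO2 -> citrate; citrate lyase -> AcCoA + OAA -> aspartate
METABOLITE	gln.x	5	source
METABOLITE	co2	1	source
METABOLITE	accoa.x	2	sink
METABOLITE	asp.x	4	sink
METABOLITE	glu	5	balanced
METABOLITE	akg	5	balanced
METABOLITE	cit	6	balanced
METABOLITE	accoa	2	balanced
METABOLITE	oaa	4	balanced
METABOLITE	asp	4	balanced
REACTION	GLS	irr	gln.x (abcde) -> glu (abcde)
REACTION	GDH	irr	glu (abcde) -> akg (abcde)
REACTION	IDHR	irr	akg (abcde) + co2 (f) -> cit (abcdef)
REACTION	ACL	irr	cit (abcdef) -> accoa (ab) + oaa (cdef)
REACTION	ACCOUT	irr	accoa (ab) -> accoa.x (ab)
REACTION	AST	irr	oaa (abcd) -> asp (abcd)
REACTION	ASPOUT	irr	asp (abcd) -> asp.x (abcd)
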