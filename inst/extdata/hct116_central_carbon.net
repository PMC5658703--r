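# central carbon metabolism of an HCT116-like cell line:
# glycolysis, oxidative + non-oxidative PPP, TCA cycle with succinate
# symmetry, reversible IDH (reductive carboxylation), ATP-citrate lyase,
# glutaminolysis, secretion and uptake reactions, glycogen branch, and a
# lumped protein-synthesis drain.
METABOLITE	glc.x	6	source
METABOLITE	gln.x	5	source
METABOLITE	co2	1	source
METABOLITE	eaa.x	6	source
METABOLITE	lac.x	3	sink
METABOLITE	glu.x	5	sink
METABOLITE	ala.x	3	sink
METABOLITE	asp.x	4	sink
METABOLITE	glyc.x	6	sink
METABOLITE	protein.x	0	sink
METABOLITE	g6p	6	balanced
METABOLITE	f6p	6	balanced
METABOLITE	gap	3	balanced
METABOLITE	p5p	5	balanced
METABOLITE	s7p	7	balanced
METABOLITE	e4p	4	balanced
METABOLITE	pyr	3	balanced
METABOLITE	accoa	2	balanced
METABOLITE	cit	6	balanced
METABOLITE	akg	5	balanced
METABOLITE	suc	4	balanced
METABOLITE	mal	4	balanced
METABOLITE	oaa	4	balanced
METABOLITE	glu	5	balanced
METABOLITE	gln	5	balanced
METABOLITE	asp	4	balanced
METABOLITE	ala	3	balanced
METABOLITE	eaa	6	balanced
REACTION	HK	irr	glc.x (abcdef) -> g6p (abcdef)
REACTION	PGI	rev	g6p (abcdef) -> f6p (abcdef)
REACTION	PFK	irr	f6p (abcdef) -> gap (cba) + gap (def)
REACTION	PK	irr	gap (abc) -> pyr (abc)
REACTION	LDH	irr	pyr (abc) -> lac.x (abc)
REACTION	G6PDH	irr	g6p (abcdef) -> p5p (bcdef) + co2 (a)
REACTION	TK1	rev	p5p (abcde) + p5p (fghij) -> s7p (abfghij) + gap (cde)
REACTION	TA	rev	s7p (abcdefg) + gap (hij) -> f6p (abchij) + e4p (defg)
REACTION	TK2	rev	p5p (abcde) + e4p (fghi) -> f6p (abfghi) + gap (cde)
REACTION	PDH	irr	pyr (abc) -> accoa (bc) + co2 (a)
REACTION	PC	irr	pyr (abc) + co2 (d) -> oaa (abcd)
REACTION	ME	irr	mal (abcd) -> pyr (abc) + co2 (d)
REACTION	CS	irr	accoa (ab) + oaa (cdef) -> cit (abcdef)
REACTION	IDH	rev	cit (abcdef) -> akg (abcde) + co2 (f)
REACTION	AKGDH	irr	akg (abcde) -> suc (bcde) + co2 (a)
REACTION	SDH	rev	suc (abcd) -> mal (abcd)
MAP2	suc (abcd) -> mal (dcba)
REACTION	MDH	rev	mal (abcd) -> oaa (abcd)
REACTION	ACL	irr	cit (abcdef) -> accoa (ab) + oaa (cdef)
REACTION	GLNUP	irr	gln.x (abcde) -> gln (abcde)
REACTION	GLS	irr	gln (abcde) -> glu (abcde)
REACTION	GDH	rev	glu (abcde) -> akg (abcde)
REACTION	AST	rev	oaa (abcd) -> asp (abcd)
REACTION	ALT	rev	pyr (abc) -> ala (abc)
REACTION	GLUOUT	irr	glu (abcde) -> glu.x (abcde)
REACTION	ALAOUT	irr	ala (abc) -> ala.x (abc)
REACTION	ASPOUT	irr	asp (abcd) -> asp.x (abcd)
REACTION	GLYS	irr	g6p (abcdef) -> glyc.x (abcdef)
REACTION	EAAUP	irr	eaa.x (abcdef) -> eaa (abcdef)
REACTION	PROT	irr	asp (abcd) + glu (efghi) + ala (jkl) + gln (mnopq) + eaa (rstuvw) -> protein.x
ANNOTATION	electron_pairs	PK=1,PDH=1,AKGDH=1,SDH=1,MDH=1,IDH=1,GDH=1,ME=1,LDH=-1
ANNOTATION	o2_per_pair	0.5
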