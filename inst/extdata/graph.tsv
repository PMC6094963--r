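term1	term2	weight	relation
angoisse	peur	45	
angoisse	stress	40	
angoisse	angoissant	35	morph
angoisse	angoissee	28	morph
anxiete	anxieux	50	morph
anxiete	inquietude	42	
anxiete	angoisse	38	
depression	tristesse	60	
depression	depressif	55	morph
depression	deprime	48	morph
phobie	peur	38	
phobie	phobique	30	morph
panique	frayeur	20	
panique	affolement	12	
insomnie	sommeil	33	
insomnie	insomniaque	25	morph
nervosite	nerveux	44	morph
nervosite	enervement	22	
stress	tension	25	
stress	stressant	21	morph
boulimie	boulimique	26	morph
agoraphobie	agoraphobe	31	morph
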