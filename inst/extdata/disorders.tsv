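term	code	group	variants
dépression	F32	F32	depressif,depressive,deprime
déprime	F32.9	F32	
anxiété	F41.9	F41	anxieux,anxieuse
angoisse	F41.0	F41	angoisses,angoissee
crise d'angoisse	F41.0	F41	crises d'angoisse
panique	F41.0	F41	paniques
attaque de panique	F41.0	F41	attaques de panique
phobie	F40	F40	phobies,phobique
agoraphobie	F40.0	F40	agoraphobe
phobie sociale	F40.1	F40	peur sociale
stress	F43.9	F43	stresse,stressee
insomnie	F51.0	F51	insomnies
nervosité	F48.0	F48	nerveux,nerveuse
trouble bipolaire	F31	F31	bipolaire
boulimie	F50.2	F50	boulimique
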