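word	lemma	root
nerveux	nerveux	nerv
nerveuse	nerveux	nerv
nerveusement	nerveusement	nerv
nervosite	nervosite	nerv
angoisse	angoisse	angoiss
angoisses	angoisse	angoiss
angoissant	angoissant	angoiss
angoissee	angoisser	angoiss
anxiete	anxiete	anxi
anxieux	anxieux	anxi
anxieuse	anxieux	anxi
anxieusement	anxieusement	anxi
depression	depression	depress
depressif	depressif	depress
depressive	depressif	depress
deprime	deprime	depress
phobie	phobie	phob
phobies	phobie	phob
phobique	phobique	phob
panique	panique	paniq
paniques	panique	paniq
paniquer	paniquer	paniq
stress	stress	stress
stresse	stresser	stress
stressee	stresser	stress
stressant	stressant	stress
insomnie	insomnie	insomn
insomnies	insomnie	insomn
insomniaque	insomniaque	insomn
boulimie	boulimie	boulim
boulimique	boulimique	boulim
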