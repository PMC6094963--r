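angoisses	angoisse
crises	crise
paniques	panique
attaques	attaque
phobies	phobie
insomnies	insomnie
anxieuse	anxieux
nerveuse	nerveux
depressive	depressif
stressee	stresse
angoissee	angoisse
prends	prendre
prend	prendre
pris	prendre
prise	prendre
prises	prendre
bois	boire
comprimes	comprime
boites	boite
effets	effet
soirs	soir
semaines	semaine
reponses	reponse
allez	aller
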