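code	label
F40.0	agoraphobe
F40.0	peur sociale
F40	peur des foules
F41.0	attaque de panique
F41.9	trouble anxieux
F41.9	trouble anxièux
F32	episode depressif
F32	trouble depressif
F32.9	coup de blues
F51.0	trouble du sommeil
F48.0	etat de nerfs
F31	maniaco depressif
F50.2	hyperphagie
F43.9	tension nerveuse
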