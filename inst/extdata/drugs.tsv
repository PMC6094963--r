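surface	atc
leeloo	G03AA07
optilova	G03AA07
minidril	G03AA06
trinordiol	G03AA06
jasmine	G03AA12
jasminelle	G03AA12
cerazette	G03AC09
optimizette	G03AC09
qlaira	G03AB08
utrogestan	G03DA04
xanax	N05BA12
lexomil	N05BA08
temesta	N05BA06
valium	N05BA01
seresta	N05BA04
atarax	N05BB01
stilnox	N05CF02
imovane	N05CF01
loxapac	N05AH01
prozac	N06AB03
deroxat	N06AB05
seroplex	N06AB10
zoloft	N06AB06
effexor	N06AX16
laroxyl	N06AA09
anafranil	N06AA04
doliprane	N02BE01
aspegic	B01AC06
spasfon	A03AX12
smecta	A07BC05
amoxicilline	J01CA04
ventoline	R03AC02
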