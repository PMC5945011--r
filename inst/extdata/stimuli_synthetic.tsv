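picture	category	onset	related_distractor	unrelated_distractor
been	lichaamsdeel	b	arm	tafel
stoel	meubel	s	tafel	kat
hond	huisdier	h	kat	bus
fiets	voertuig	f	bus	melk
kaas	zuivel	k	melk	struik
boom	plant	b	struik	maan
zon	hemellichaam	z	maan	vork
mes	bestek	m	vork	krijt
pen	schrijfgerei	p	krijt	schuur
huis	gebouw	h	schuur	krab
vis	zeedier	v	krab	mees
duif	vogel	d	mees	tram
trein	spoorvoertuig	t	tram	kop
glas	vaatwerk	g	kop	wieg
bed	slaapmeubel	b	wieg	rat
muis	knaagdier	m	rat	vest
jas	kleding	j	vest	pruim
peer	fruit	p	pruim	mist
wolk	weerbeeld	w	mist	boot
schip	vaartuig	s	boot	slot
kerk	bouwwerk	k	slot	beer
leeuw	roofdier	l	beer	ham
worst	vleeswaar	w	ham	trom
fluit	instrument	f	trom	spin
mier	insect	m	spin	schaap
koe	vee	k	schaap	tulp
roos	bloem	r	tulp	eend
zwaan	watervogel	z	eend	oor
neus	gezichtsdeel	n	oor	pad
slang	reptiel	s	pad	dal
berg	landschap	b	dal	draad
touw	materiaal	t	draad	bel
klok	uurwerk	k	bel	raam
deur	bouwdeel	d	raam	schoen
laars	schoeisel	l	schoen	komeet
ster	ruimteobject	s	komeet	tunnel
dijk	infrastructuur	d	tunnel	long
hart	orgaan	h	long	vlam
vuur	element	v	vlam	riem
das	accessoire	d	riem	arm
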