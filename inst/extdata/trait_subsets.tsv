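subset_name	trait_id
energy	coxA
energy	coxB
energy	coxC
energy	ccoN
energy	ccoO
energy	cydA
energy	cydB
energy	cyoA
energy	qoxA
energy	nuoF
energy	nuoG
energy	ndh
energy	sdhA
energy	sdhB
energy	frdA
energy	atpA
energy	atpD
energy	atpF
energy	petA
energy	petB
energy	petC
energy	psbA
energy	psbD
energy	psaA
energy	psaB
energy	pufM
energy	pufL
energy	bchL
energy	pr
energy	rbcL
energy	rbcS
energy	aclB
energy	mcrA
energy	porA
energy	pflD
energy	hyaB
energy	hydA
substrate	pgi
substrate	pfkA
substrate	fbaA
substrate	gapA
substrate	pgk
substrate	pyk
substrate	ppdK
substrate	pckA
substrate	mdh
substrate	sucA
substrate	sucB
substrate	fumC
substrate	acnA
substrate	icd
substrate	gltA
substrate	korA
substrate	amyA
substrate	glgP
substrate	malZ
substrate	xylA
substrate	araA
substrate	rhaA
substrate	manA
substrate	fucA
substrate	galK
substrate	lacZ
substrate	bglX
substrate	chiA
substrate	celB
substrate	xynA
substrate	pelA
substrate	pulA
substrate	nagZ
substrate	treY
substrate	scrK
substrate	prpB
substrate	prpC
substrate	acs
substrate	ackA
substrate	pta
substrate	adhE
substrate	aldH
substrate	ldhA
substrate	badA
substrate	hcaB
substrate	paaK
substrate	fadD
CO	coxL
CO	coxM
CO	coxS
H2	hyaB
H2	hybC
H2	hoxH
H2	hndD
H2	mvhA
H2	echA
N	nifH
N	nifD
N	nifK
N	amoA
N	hao
N	nxrA
N	narG
N	napA
N	nirK
N	nirS
N	norB
N	nosZ
N	nrfA
N	ureC
S	dsrA
S	dsrB
S	aprA
S	sat
S	soxB
S	soxC
S	sqr
S	fcc
S	sor
CAZy	GH1
CAZy	GH2
CAZy	GH3
CAZy	GH13
CAZy	GH23
CAZy	GH73
CAZy	GH107
CAZy	GT2
CAZy	GT4
CAZy	GT28
CAZy	GT51
CAZy	CE4
CAZy	CE11
CAZy	CBM50
CAZy	CBM44
CAZy	AA2
CAZy	AA3
CAZy	AA4
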