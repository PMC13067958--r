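marker_id	gene_name	products
bsh	bsh	Choloylglycine hydrolase|Bile salt hydrolase
gadA	gadA	Glutamate decarboxylase alpha
gadB	gadB	Glutamate decarboxylase beta
gadC	gadC	Glutamate/gamma-aminobutyrate antiporter
srtA	srtA	Sortase A
lpxtg	NA	LPXTG cell wall anchor domain-containing protein
spaA	spaA	Pilus backbone protein SpaA
spaB	spaB	Pilus ancillary protein SpaB
spaC	spaC	Pilus tip adhesin SpaC
pilin	NA	Fimbrial protein
eps	epsB	Exopolysaccharide biosynthesis protein
wzx	wzx	Polysaccharide flippase
wzy	wzy	Polysaccharide polymerase
wzb	wzb	Tyrosine-protein phosphatase Wzb
wzc	wzc	Tyrosine-protein kinase Wzc
gtf	gtfA	Glucosyltransferase
rfb	rfbB	dTDP-glucose 4,6-dehydratase
ugd	ugd	UDP-glucose 6-dehydrogenase
gnd	gnd	6-phosphogluconate dehydrogenase
groEL	groEL	60 kDa chaperonin|Chaperonin GroEL
dnaK	dnaK	Chaperone protein DnaK
clpC	clpC	ATP-dependent Clp protease ATP-binding subunit ClpC
clpP	clpP	ATP-dependent Clp protease proteolytic subunit
cspA	cspA	Cold shock protein CspA
sodA	sodA	Superoxide dismutase
kat	katA	Catalase
ahpC	ahpC	Alkyl hydroperoxide reductase subunit C
fol	folA	Dihydrofolate reductase|Dihydropteroate synthase
rib	ribB	Riboflavin synthase|GTP cyclohydrolase II
thi	thiE	Thiamine-phosphate synthase
atpA	atpA	ATP synthase subunit alpha
atpB	atpB	ATP synthase subunit a
atpC	atpC	ATP synthase epsilon chain
atpD	atpD	ATP synthase subunit beta
atpE	atpE	ATP synthase subunit c
atpF	atpF	ATP synthase subunit b
atpG	atpG	ATP synthase gamma chain
atpH	atpH	ATP synthase subunit delta
arcA	arcA	Arginine deiminase
arcB	arcB	Ornithine carbamoyltransferase
arcC	arcC	Carbamate kinase
arcD	arcD	Arginine/ornithine antiporter
arcT	arcT	Aminotransferase ArcT
mub	mub	Mucus-binding protein
cna	cna	Collagen-binding protein
fbpA	fbpA	Fibronectin-binding protein A
slpA	slpA	S-layer protein A
slpB	slpB	S-layer protein B
dltA	dltA	D-alanyl carrier protein ligase
bacteriocin_general	NA	Bacteriocin biosynthesis protein|Lantibiotic biosynthesis protein
pln	plnB	Plantaricin biosynthesis protein PlnB
pdu	pduC	Propanediol dehydratase large subunit
cob	cobD	Cobalamin biosynthesis protein CobD
pts	ptsI	PTS system EIIAB component
lac	lacZ	Beta-galactosidase
gal	galK	Galactokinase
man	manA	Mannose-6-phosphate isomerase
rbs	rbsK	Ribokinase
cas	cas9	CRISPR-associated protein Cas9
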