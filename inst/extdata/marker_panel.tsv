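marker_id	pattern	fields	category	subcategory
bsh	\b(bsh|choloylglycine hydrolase|bile salt hydrolase)\b	gene|product	Acid tolerance and energy metabolism	Bile salt resistance
gadA	\b(gadA|glutamate decarboxylase alpha)\b	gene|product	Amino acid and general metabolism	GABA production
gadB	\b(gadB|glutamate decarboxylase beta)\b	gene|product	Amino acid and general metabolism	GABA production
gadC	\b(gadC|glutamate[/ -]gamma-aminobutyrate antiporter)\b	gene|product	Amino acid and general metabolism	GABA production
srtA	\b(srtA|sortase)\b	gene|product	Cell envelope and EPS biosynthesis	Surface adhesion proteins
lpxtg	\bLPXTG\b	gene|product|note	Cell envelope and EPS biosynthesis	Surface adhesion proteins
spaA	\b(spaA|pilus backbone protein)\b	gene|product	Cell envelope and EPS biosynthesis	Biofilm adhesion proteins
spaB	\b(spaB|pilus ancillary protein)\b	gene|product	Cell envelope and EPS biosynthesis	Biofilm adhesion proteins
spaC	\b(spaC|pilus tip adhesin)\b	gene|product	Cell envelope and EPS biosynthesis	Biofilm adhesion proteins
pilin	\b(pilin|fimbrial protein)\b	gene|product	Cell envelope and EPS biosynthesis	Biofilm adhesion proteins
eps	\b(eps[A-Z]|exopolysaccharide biosynthesis protein)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
wzx	\b(wzx|polysaccharide flippase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
wzy	\b(wzy|polysaccharide polymerase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
wzb	\b(wzb|tyrosine-protein phosphatase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
wzc	\b(wzc|tyrosine-protein kinase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
gtf	\b(gtf[A-Z]?|glucosyltransferase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
rfb	\b(rfb[A-Z]|dTDP-glucose 4,6-dehydratase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
ugd	\b(ugd|UDP-glucose 6-dehydrogenase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
gnd	\b(gnd|6-phosphogluconate dehydrogenase)\b	gene|product	Cell envelope and EPS biosynthesis	EPS biosynthesis
groEL	\b(groEL|60 kDa chaperonin|chaperonin GroEL)\b	gene|product	Cold and heat stress tolerance	Heat stress tolerance
dnaK	\b(dnaK|chaperone protein DnaK)\b	gene|product	Cold and heat stress tolerance	Heat stress tolerance
clpC	\b(clpC|Clp protease ATP-binding subunit)\b	gene|product	Cold and heat stress tolerance	Heat stress tolerance
clpP	\b(clpP|Clp protease proteolytic subunit)\b	gene|product	Cold and heat stress tolerance	Heat stress tolerance
cspA	\b(csp[A-E]|cold[ -]shock protein)\b	gene|product	Cold and heat stress tolerance	Cold stress tolerance
sodA	\b(sodA|superoxide dismutase)\b	gene|product	Cold and heat stress tolerance	Oxidative stress tolerance
kat	\b(kat[AE]?|catalase)\b	gene|product	Cold and heat stress tolerance	Oxidative stress tolerance
ahpC	\b(ahpC|alkyl hydroperoxide reductase)\b	gene|product	Cold and heat stress tolerance	Oxidative stress tolerance
fol	\b(fol[A-P]|dihydrofolate (reductase|synthase)|dihydropteroate synthase)\b	gene|product	Vitamin and cofactor biosynthesis	Folate biosynthesis
rib	\b(rib[A-HT]|riboflavin (biosynthesis|synthase)|GTP cyclohydrolase II)\b	gene|product	Vitamin and cofactor biosynthesis	Riboflavin biosynthesis
thi	\b(thi[A-OS]|thiamine-phosphate synthase|thiamine biosynthesis)\b	gene|product	Vitamin and cofactor biosynthesis	Thiamine biosynthesis
atpA	\b(atpA|ATP synthase subunit alpha)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
atpB	\b(atpB|ATP synthase subunit a)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
atpC	\b(atpC|ATP synthase epsilon chain)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
atpD	\b(atpD|ATP synthase subunit beta)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
atpE	\b(atpE|ATP synthase subunit c)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
atpF	\b(atpF|ATP synthase subunit b)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
atpG	\b(atpG|ATP synthase gamma chain)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
atpH	\b(atpH|ATP synthase subunit delta)\b	gene|product	Acid tolerance and energy metabolism	F0F1 ATPase acid tolerance
arcA	\b(arcA|arginine deiminase)\b	gene|product	Acid tolerance and energy metabolism	Arginine deiminase system
arcB	\b(arcB|ornithine carbamoyltransferase)\b	gene|product	Acid tolerance and energy metabolism	Arginine deiminase system
arcC	\b(arcC|carbamate kinase)\b	gene|product	Acid tolerance and energy metabolism	Arginine deiminase system
arcD	\b(arcD|arginine[/ -]ornithine antiporter)\b	gene|product	Acid tolerance and energy metabolism	Arginine deiminase system
arcT	\b(arcT|aminotransferase ArcT)\b	gene|product	Acid tolerance and energy metabolism	Arginine deiminase system
mub	\b(mub|mucus[ -]binding protein)\b	gene|product	Cell envelope and EPS biosynthesis	Gut persistence factors
cna	\b(cna|collagen[ -]binding protein)\b	gene|product	Cell envelope and EPS biosynthesis	Surface adhesion proteins
fbpA	\b(fbpA|fibronectin[ -]binding protein)\b	gene|product	Cell envelope and EPS biosynthesis	Surface adhesion proteins
slpA	\b(slpA|S-layer protein A)\b	gene|product	Cell envelope and EPS biosynthesis	Surface adhesion proteins
slpB	\b(slpB|S-layer protein B)\b	gene|product	Cell envelope and EPS biosynthesis	Surface adhesion proteins
dltA	\b(dltA|D-alanine--poly\(glycerophosphate\) ligase|D-alanyl carrier protein ligase)\b	gene|product	Cell envelope and EPS biosynthesis	Cell envelope D-alanylation
bacteriocin_general	\b(bacteriocin|lantibiotic|RiPP|ribosomally synthesi[sz]ed)\b	gene|product|note	Bacteriocin and antimicrobial peptide production	Bacteriocin biosynthesis
pln	\b(pln[A-Z]|plantaricin)\b	gene|product	Bacteriocin and antimicrobial peptide production	Plantaricin system
pdu	\b(pdu[A-Z]|propanediol dehydratase|propanediol utilization)\b	gene|product	Bacteriocin and antimicrobial peptide production	Reuterin system
cob	\b(cob[A-Z]|cbi[A-Z]|cobalamin biosynthesis)\b	gene|product	Bacteriocin and antimicrobial peptide production	Reuterin system
pts	\b(pts[A-Z]?|phosphotransferase system|PTS system)\b	gene|product	Carbohydrate utilization and transport	PTS systems
lac	\b(lac[A-Z]|beta-galactosidase|lactose permease)\b	gene|product	Carbohydrate utilization and transport	Sugar transporters
gal	\b(gal[A-Z]|galactokinase|alpha-galactosidase)\b	gene|product	Carbohydrate utilization and transport	Sugar transporters
man	\b(man[A-Z]|mannose-6-phosphate isomerase|mannose permease)\b	gene|product	Carbohydrate utilization and transport	Sugar transporters
rbs	\b(rbs[A-Z]|ribose import|ribokinase)\b	gene|product	Carbohydrate utilization and transport	Sugar transporters
cas	\b(cas[0-9][a-z]?|CRISPR-associated)\b	gene|product	Defense systems and CRISPR-Cas	CRISPR-Cas systems
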