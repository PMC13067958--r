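bacteriocin_name	subclass
Nisin A	I
Nisin F	I
Lacticin 3147 A1	I
Lacticin 3147 A2	I
Mutacin II	I
Salivaricin B	I
Pediocin	IIa
Pediocin PA-1	IIa
Sakacin P	IIa
Sakacin G	IIa
Curvacin A	IIa
Pentocin	IIa
Plantaricin 423	IIa
Carnocin CP52	IIa
Enterocin X alpha	IIb
Enterocin X beta	IIb
Plantaricin E	IIb
Plantaricin F	IIb
Plantaricin J	IIb
Plantaricin K	IIb
Plantaricin NC8 alpha	IIb
Plantaricin NC8 beta	IIb
Plantaricin S alpha	IIb
Plantaricin S beta	IIb
Salivaricin P	IIb
Lactacin F lafA	IIb
Lactacin F lafX	IIb
Brochocin C	IIb
Acidocin LF221B	IIb
MR10A	IIb
MR10B	IIb
Acidocin B	IIc
Gassericin A	IIc
Plantaricin A	IId
Lacticin Z	IId
Lacticin Q	IId
Sakacin Q	IId
LSEI 2386	IId
LS2 bacteriocin	IId
Bovicin 255	IId
Closticin 574	IId
Enterocin NKR-5-3A	IId
Enterolysin A	III
Helveticin J	III
Zoocin A	III
Putative bacteriocin	other
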