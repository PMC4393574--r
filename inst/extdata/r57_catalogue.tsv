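gene	chromosome	region	position	ref	alt	protein_change	zygosity	sift_score	group_tag	offset_direction
NRG1	IV	CDS	137	C	A	P46Q	homo	0	NA	NA
UBP7	IX	CDS	2466	T	A	N822K	homo	0.33	a	NA
ART5	VII	CDS	454	C	A	L152I	het	0.17	a	NA
SSA1	I	CDS	91	C	A	Q31K	het	0	a	NA
GDH1	XV	CDS	47	C	T	S16F	het	0	b	NA
GDH1	XV	CDS	68	T	G	F23C	het	0	b	NA
ARO1	IV	CDS	1283	C	T	S428F	het	0	b	NA
ARO1	IV	CDS	1284	C	T	silent	het	NA	b	NA
STE5	IV	CDS	512	C	T	S171F	het	0	b	NA
STE5	IV	CDS	2649	T	C	silent	het	NA	b	NA
MAL11	VII	CDS	310	C	T	P104S	het	0	b	NA
MAL11	VII	CDS	482	T	A	M161K	het	0.02	b	NA
GSH1	X	UTR5	73	T	A	NA	het	NA	c	5prime
PBP1	VII	UTR5	191	T	C	NA	het	NA	c	5prime
FIT3	XV	UTR3	42	C	T	NA	het	NA	c	3prime
NOP58	XV	UTR3	25	A	T	NA	het	NA	c	3prime
YNL058C	XIV	CDS	7	A	G	K3E	het	0.42	d	NA
DOP1	IV	CDS	40	A	T	N14Y	het	0.05	d	NA
TOF2	XI	CDS	2141	C	T	S714L	het	0.27	d	NA
SGO1	XV	CDS	575	C	A	S192Y	het	0.03	d	NA
BCS1	IV	intergenic	43	NA	NA	NA	het	NA	NA	3prime
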