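protein	accession	position	wt	var	phenotype
SRY	Q05066	2	R	C	46,XY sex reversal
SOX9	P48436	4	N	K	Campomelic dysplasia
SOX10	P56693	6	L	P	Waardenburg-Hirschsprung disease
SOX2	P48431	7	S	F	Microphthalmia
SRY	Q05066	9	F	S	46,XY sex reversal
SOX9	P48436	10	G	D	Campomelic dysplasia
SOX10	P56693	12	W	R	Waardenburg-Hirschsprung disease
SOX2	P48431	13	E	K	Microphthalmia
SOX9	P48436	16	A	V	Campomelic dysplasia
SOX9	P48436	18	R	G	Campomelic dysplasia
SOX10	P56693	20	W	R	Waardenburg-Hirschsprung disease
SOX2	P48431	22	M	T	Microphthalmia
SRY	Q05066	25	K	E	46,XY sex reversal
SOX9	P48436	27	P	L	Campomelic dysplasia
SOX10	P56693	29	Y	C	Waardenburg-Hirschsprung disease
SOX2	P48431	31	F	S	Microphthalmia
SRY	Q05066	32	V	E	46,XY sex reversal
SOX9	P48436	34	Q	P	Campomelic dysplasia
SOX10	P56693	36	H	Y	Waardenburg-Hirschsprung disease
SOX2	P48431	38	D	N	Microphthalmia
SRY	Q05066	40	F	L	46,XY sex reversal
SOX9	P48436	43	I	T	Campomelic dysplasia
HMGB1	P09429	45	A	E	Gastric carcinoma cell line
SOX2	P48431	48	R	G	Microphthalmia
SRY	Q05066	51	Y	H	46,XY sex reversal
SOX9	P48436	53	L	P	Campomelic dysplasia
SOX10	P56693	56	T	I	Waardenburg-Hirschsprung disease
SOX2	P48431	58	K	N	Microphthalmia
SRY	Q05066	60	E	K	46,XY sex reversal
SOX9	P48436	63	S	F	Campomelic dysplasia
SOX10	P56693	66	G	R	Waardenburg-Hirschsprung disease
SOX2	P48431	70	P	L	Microphthalmia
HMGB1	P09429	74	K	E	Gastric carcinoma cell line
SRY	Q05066	2	R	H	46,XY sex reversal
SOX9	P48436	4	N	Q	Campomelic dysplasia
SOX10	P56693	6	L	M	Waardenburg-Hirschsprung disease
SOX2	P48431	7	S	W	Microphthalmia
SRY	Q05066	9	F	L	46,XY sex reversal
SOX9	P48436	10	G	E	Campomelic dysplasia
SOX10	P56693	12	W	K	Waardenburg-Hirschsprung disease
SOX2	P48431	13	E	A	Microphthalmia
SOX9	P48436	18	R	D	Campomelic dysplasia
SOX10	P56693	20	W	T	Waardenburg-Hirschsprung disease
SOX2	P48431	22	M	N	Microphthalmia
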