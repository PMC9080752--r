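opsin_class	bovine_site	from	to	shift_nm	source
RH1	299	S	A	-2	site-directed mutagenesis, rod opsin literature
RH1	164	A	S	NA	known rod tuning site; effect not quantified here
SWS2	265	W	T	-29	SWS2 mutagenesis literature
SWS2	46	F	V	8	SWS2 mutagenesis literature
SWS2	164	G	A	NA	known SWS2 tuning site; effect not quantified here
RH2	88	M	C	3	zebrafish RH2 mutagenesis
RH2	88	C	A	-3	zebrafish RH2 mutagenesis
RH2	112	I	V	1	zebrafish RH2 mutagenesis
RH2	266	T	V	-2	zebrafish RH2 mutagenesis
RH2	185	T	C	-4	zebrafish RH2 mutagenesis
RH2	97	T	A	-8	RH2 mutagenesis literature
RH2	151	N	S	4	zebrafish RH2 mutagenesis
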