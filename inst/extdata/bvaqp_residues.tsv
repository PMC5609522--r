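# Diagnostic residues per sugar beet aquaporin: dual NPA motifs (loop B / loop E),
# ar/R selectivity filter (H2, H5, LE1, LE2) and Froger positions (P1-P5).
# NA marks cells left blank in the curated source table.
label	subfamily	npa_lb	npa_le	h2	h5	le1	le2	p1	p2	p3	p4	p5
BvPIP1;1	PIP	NPA	NPA	F	H	T	R	Q	S	A	F	W
BvPIP1;2	PIP	NPA	NPA	F	H	T	R	Q	S	A	NA	NA
BvPIP1;3	PIP	NPA	NPA	F	H	T	R	Q	S	A	F	W
BvPIP2;1	PIP	NPA	NPA	F	H	T	R	Q	S	A	F	W
BvPIP2;2	PIP	NPA	NPA	F	H	T	R	Q	S	A	F	W
BvPIP2;3	PIP	NPA	NPA	F	H	T	R	Q	S	A	F	W
BvPIP2;4	PIP	NPA	NPA	F	H	T	R	M	S	A	F	W
BvTIP1;1	TIP	NPA	NPA	H	I	A	V	T	S	A	Y	W
BvTIP1;2	TIP	NPA	NPA	H	I	A	V	T	S	A	Y	W
BvTIP1;3	TIP	NPA	NPA	H	I	A	V	T	S	A	Y	W
BvTIP2;1	TIP	NPA	NPA	H	I	G	R	T	S	A	Y	W
BvTIP2;2	TIP	NPA	NPA	H	I	G	R	T	S	A	Y	W
BvTIP3;1	TIP	NPA	NPA	H	I	A	R	T	A	A	Y	W
BvTIP4;1	TIP	NPA	NPA	H	I	A	R	T	S	A	Y	W
BvTIP5;1	TIP	NPA	NPA	N	V	G	Y	T	S	A	Y	W
BvNIP1;1	NIP	NPA	NPA	W	V	A	R	F	S	A	Y	L
BvNIP4;1	NIP	NPA	NPA	W	V	A	R	F	S	A	Y	I
BvNIP4;2	NIP	NPS	NPA	W	A	A	R	L	S	A	Y	I
BvNIP5;1	NIP	NPS	NPV	A	I	G	R	F	T	A	Y	M
BvNIP5;2	NIP	NPS	NPV	A	I	A	R	F	T	A	Y	M
BvNIP6;1	NIP	NPS	NPV	S	I	G	R	F	T	A	Y	F
BvNIP6;2	NIP	NPA	NPA	S	I	G	R	Y	T	A	Y	M
BvNIP6;3	NIP	NPA	NPA	S	I	A	R	Y	T	A	Y	L
BvNIP7;1	NIP	NPA	NPA	A	V	G	R	F	S	A	Y	F
BvSIP1;1alpha	SIP	NPT	NPA	I	V	P	N	M	A	A	Y	W
BvSIP1;1beta	SIP	NPT	NPA	V	V	P	N	M	A	A	Y	W
BvSIP2;1	SIP	NPL	NPA	S	N	G	S	F	V	A	Y	W
BvXIP1;1	XIP	NPT	NPA	V	S	A	R	F	C	A	F	W
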