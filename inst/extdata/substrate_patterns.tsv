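# Substrate-specificity SDP patterns: nine allowed-residue sets per substrate
# (slash-delimited). class 'typical' = canonical transporter signature;
# class 'novel' = single-position variants described for this family.
substrate	class	sdp1	sdp2	sdp3	sdp4	sdp5	sdp6	sdp7	sdp8	sdp9
NH3	typical	F/T	K/L/N/V	F/T	V/L/T	A	D/S	A/H/L	E/P/S	A/R/T
boric_acid	typical	T/V	I/V	H/I	P	E	I/L	I/L/T	A/T	A/G/K/P
CO2	typical	I/L/V	I	C	A	I/V	D	W	D	W
H2O2	typical	A/S	A/G	L/V	A/F/L/T/V	I/L/V	H/I/L/Q	F/Y	A/V	P
silicic_acid	typical	C/S	F/Y	A/E/L	H/R/Y	G	K/N/T	R	E/S/T	A/K/P/T
urea	typical	H	P	F/I/L/T	A/C/F/L	L/M	A/G/P	G/S	G/S	N
CO2	novel	I/L/V	M	C	A	I/V	D/H/K	W	D	W
NH3	novel	F/T	H	F/T	V/L/T	A	D/S	A/H/L	E/P/S	A/R/T
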