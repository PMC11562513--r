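codon	aa	freq
GCC	A	27.7
GCT	A	18.4
GCA	A	15.8
GCG	A	7.4
TGC	C	12.6
TGT	C	10.6
GAC	D	25.1
GAT	D	21.8
GAG	E	39.6
GAA	E	29.0
TTC	F	20.3
TTT	F	17.6
GGC	G	22.2
GGA	G	16.5
GGG	G	16.5
GGT	G	10.8
CAC	H	15.1
CAT	H	10.9
ATC	I	20.8
ATT	I	16.0
ATA	I	7.5
AAG	K	31.9
AAA	K	24.4
CTG	L	39.6
CTC	L	19.6
CTT	L	13.2
TTG	L	12.9
TTA	L	7.7
CTA	L	7.2
ATG	M	22.0
AAC	N	19.1
AAT	N	17.0
CCC	P	19.8
CCT	P	17.5
CCA	P	16.9
CCG	P	6.9
CAG	Q	34.2
CAA	Q	12.3
AGA	R	12.2
AGG	R	12.0
CGG	R	11.4
CGC	R	10.4
CGA	R	6.2
CGT	R	4.5
AGC	S	19.5
TCC	S	17.7
TCT	S	15.2
TCA	S	12.2
AGT	S	12.1
TCG	S	4.4
ACC	T	18.9
ACA	T	15.1
ACT	T	13.1
ACG	T	6.1
GTG	V	28.1
GTC	V	14.5
GTT	V	11.0
GTA	V	7.1
TGG	W	13.2
TAC	Y	15.3
TAT	Y	12.2
TGA	*	1.6
TAA	*	1.0
TAG	*	0.8
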