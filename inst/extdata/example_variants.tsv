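Sample	Gene	Exon	Protein_position	Amino_acids	Consequence	DOMAINS	PolyPhen	SIFT
S0001	PIK3CA	21/21	1047/1068	H/R	missense	Pfam:PF00454	probably_damaging(0.981)	deleterious(0.01)
S0002	PIK3CA	21/21	1047/1068	H/R	missense	Pfam:PF00454	probably_damaging(0.981)	deleterious(0.01)
S0003	PIK3CA	10/21	545/1068	E/K	missense	Pfam:PF00792	possibly_damaging(0.652)	deleterious(0.03)
S0004	PIK3CA	10/21	542/1068	E/K	missense	Pfam:PF00792	benign(0.24)	tolerated(0.2)
S0005	PIK3CA	5/21	345/1068	C/S	missense	SMART:SM00142	probably_damaging(0.93)	deleterious(0.0)
S0006	GATA3	.	.	.	splice_acceptor	.	.	.
S0007	GATA3	5/6	407/444	.	frameshift	Pfam:PF00320	.	.
S0008	GATA3	4/6	335/444	R/*	stop_gained	SMART:SM00401	.	.
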