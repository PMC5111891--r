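region	location	type	ha	hp	length	direction	flag
accD-psaI	Intergenic	Homopolymeric indel	AA	-	2	Insertion
atpA-atpF	Intergenic	Homopolymeric indel	T	-	1	Insertion
atpF	Intron	Homopolymeric indel	-	T	1	Deletion
ndhI-ndhA	Intergenic	Homopolymeric indel	-	A	1	Deletion
ndhJ-ndhK	Intergenic	Homopolymeric indel	-	T	1	Deletion
psbI-trnS	Intergenic	Homopolymeric indel	-	T	1	Deletion
psbI-trnS	Intergenic	Homopolymeric indel	-	A	1	Deletion
rbcL-accD	Intergenic	Homopolymeric indel	-	A	1	Deletion
rps18-rpl20	Intergenic	Homopolymeric indel	T	-	1	Insertion
trnE-trnT	Intergenic	Homopolymeric indel	-	A	1	Deletion
trnK-rps16	Intergenic	Homopolymeric indel	A	-	1	Insertion
trnK-rps16	Intergenic	Homopolymeric indel	A	-	1	Insertion
trnL	Intron	Homopolymeric indel	-	A	1	Deletion
trnL	Intron	Homopolymeric indel	A	-	1	Insertion
trnL	Intron	Homopolymeric indel	-	T	1	Deletion
trnR-aptA	Intergenic	Homopolymeric indel	-	T	1	Deletion
atpH-atpI	Intergenic	Indel	TTTATT	-	5	Insertion	printed length 5 but six bases printed
clpP-psbB	Intergenic	Indel	-	GTCTT	5	Deletion
petL-petG	Intergenic	Indel	-	G	1	Deletion
rpoB-trnC	Intergenic	Indel	-	TGTATT	5	Deletion	printed length 5 but six bases printed
rpoB-trnC	Intergenic	Indel	TACAA	-	5	Insertion
rrn23	Coding	Indel	-	AATTAA	6	Deletion
rrn23	Coding	Indel	-	TTAATT	6	Deletion
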