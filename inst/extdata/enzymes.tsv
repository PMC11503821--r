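name	site	cut_offset
AatII	GACGTC	5
AflII	CTTAAG	1
AgeI	ACCGGT	1
ApaI	GGGCCC	5
AvrII	CCTAGG	1
BamHI	GGATCC	1
BclI	TGATCA	1
BglII	AGATCT	1
BmtI	GCTAGC	5
BspHI	TCATGA	1
BsrGI	TGTACA	1
ClaI	ATCGAT	2
DraI	TTTAAA	3
EagI	CGGCCG	1
EcoRI	GAATTC	1
EcoRV	GATATC	3
FspI	TGCGCA	3
HindIII	AAGCTT	1
HpaI	GTTAAC	3
KpnI	GGTACC	5
MfeI	CAATTG	1
MluI	ACGCGT	1
MscI	TGGCCA	3
NcoI	CCATGG	1
NdeI	CATATG	2
NheI	GCTAGC	1
NotI	GCGGCCGC	2
NruI	TCGCGA	3
NsiI	ATGCAT	5
PciI	ACATGT	1
PmlI	CACGTG	3
PstI	CTGCAG	5
PvuI	CGATCG	4
PvuII	CAGCTG	3
SacI	GAGCTC	5
SalI	GTCGAC	1
ScaI	AGTACT	3
SmaI	CCCGGG	3
SpeI	ACTAGT	1
SphI	GCATGC	5
SspI	AATATT	3
StuI	AGGCCT	3
XbaI	TCTAGA	1
XhoI	CTCGAG	1
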