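name	pattern	cut_offset
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
EcoRV	GATATC	3
DraI	TTTAAA	3
SspI	AATATT	3
XbaI	TCTAGA	1
SpeI	ACTAGT	1
NdeI	CATATG	2
NcoI	CCATGG	1
SacI	GAGCTC	5
KpnI	GGTACC	5
PstI	CTGCAG	5
SalI	GTCGAC	1
XhoI	CTCGAG	1
SmaI	CCCGGG	3
ApaI	GGGCCC	5
BglII	AGATCT	1
NheI	GCTAGC	1
AflII	CTTAAG	1
AseI	ATTAAT	2
BstBI	TTCGAA	2
AluI	AGCT	2
HaeIII	GGCC	2
RsaI	GTAC	2
TaqI	TCGA	1
MseI	TTAA	1
Sau3AI	GATC	0
NlaIII	CATG	4
HinfI	GANTC	1
DdeI	CTNAG	1
ScrFI	CCNGG	2
AvaII	GGWCC	1
StyI	CCWWGG	1
AccI	GTMKAC	2
ApoI	RAATTY	1
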