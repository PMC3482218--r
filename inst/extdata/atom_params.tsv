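residue_name	atom_name	element	radius	volume	group
ALA	N	N	1.65	15.7	N3H1
ALA	CA	C	1.87	13.5	C4H1
ALA	C	C	1.76	9.7	C3H0
ALA	O	O	1.4	15.9	O1H0
ALA	OXT	O	1.4	15.9	O1H0
ALA	CB	C	1.87	36.7	C4H3
ARG	N	N	1.65	15.7	N3H1
ARG	CA	C	1.87	13.5	C4H1
ARG	C	C	1.76	9.7	C3H0
ARG	O	O	1.4	15.9	O1H0
ARG	OXT	O	1.4	15.9	O1H0
ARG	CB	C	1.87	23.2	C4H2
ARG	CG	C	1.87	23.2	C4H2
ARG	CD	C	1.87	23.2	C4H2
ARG	NE	N	1.65	15.7	N3H1
ARG	CZ	C	1.76	9.7	C3H0
ARG	NH1	N	1.65	22.7	N3H2
ARG	NH2	N	1.65	22.7	N3H2
ASN	N	N	1.65	15.7	N3H1
ASN	CA	C	1.87	13.5	C4H1
ASN	C	C	1.76	9.7	C3H0
ASN	O	O	1.4	15.9	O1H0
ASN	OXT	O	1.4	15.9	O1H0
ASN	CB	C	1.87	23.2	C4H2
ASN	CG	C	1.76	9.7	C3H0
ASN	OD1	O	1.4	15.9	O1H0
ASN	ND2	N	1.65	22.7	N3H2
ASP	N	N	1.65	15.7	N3H1
ASP	CA	C	1.87	13.5	C4H1
ASP	C	C	1.76	9.7	C3H0
ASP	O	O	1.4	15.9	O1H0
ASP	OXT	O	1.4	15.9	O1H0
ASP	CB	C	1.87	23.2	C4H2
ASP	CG	C	1.76	9.7	C3H0
ASP	OD1	O	1.4	15.9	O1H0
ASP	OD2	O	1.4	15.9	O1H0
CYS	N	N	1.65	15.7	N3H1
CYS	CA	C	1.87	13.5	C4H1
CYS	C	C	1.76	9.7	C3H0
CYS	O	O	1.4	15.9	O1H0
CYS	OXT	O	1.4	15.9	O1H0
CYS	CB	C	1.87	23.2	C4H2
CYS	SG	S	1.85	36.7	S2H1
GLN	N	N	1.65	15.7	N3H1
GLN	CA	C	1.87	13.5	C4H1
GLN	C	C	1.76	9.7	C3H0
GLN	O	O	1.4	15.9	O1H0
GLN	OXT	O	1.4	15.9	O1H0
GLN	CB	C	1.87	23.2	C4H2
GLN	CG	C	1.87	23.2	C4H2
GLN	CD	C	1.76	9.7	C3H0
GLN	OE1	O	1.4	15.9	O1H0
GLN	NE2	N	1.65	22.7	N3H2
GLU	N	N	1.65	15.7	N3H1
GLU	CA	C	1.87	13.5	C4H1
GLU	C	C	1.76	9.7	C3H0
GLU	O	O	1.4	15.9	O1H0
GLU	OXT	O	1.4	15.9	O1H0
GLU	CB	C	1.87	23.2	C4H2
GLU	CG	C	1.87	23.2	C4H2
GLU	CD	C	1.76	9.7	C3H0
GLU	OE1	O	1.4	15.9	O1H0
GLU	OE2	O	1.4	15.9	O1H0
GLY	N	N	1.65	15.7	N3H1
GLY	CA	C	1.87	23.2	C4H2
GLY	C	C	1.76	9.7	C3H0
GLY	O	O	1.4	15.9	O1H0
GLY	OXT	O	1.4	15.9	O1H0
HIS	N	N	1.65	15.7	N3H1
HIS	CA	C	1.87	13.5	C4H1
HIS	C	C	1.76	9.7	C3H0
HIS	O	O	1.4	15.9	O1H0
HIS	OXT	O	1.4	15.9	O1H0
HIS	CB	C	1.87	23.2	C4H2
HIS	CG	C	1.76	9.7	C3H0
HIS	ND1	N	1.65	15.7	N3H1
HIS	CD2	C	1.76	21.3	C3H1
HIS	CE1	C	1.76	21.3	C3H1
HIS	NE2	N	1.65	15.7	N3H1
ILE	N	N	1.65	15.7	N3H1
ILE	CA	C	1.87	13.5	C4H1
ILE	C	C	1.76	9.7	C3H0
ILE	O	O	1.4	15.9	O1H0
ILE	OXT	O	1.4	15.9	O1H0
ILE	CB	C	1.87	13.5	C4H1
ILE	CG1	C	1.87	23.2	C4H2
ILE	CG2	C	1.87	36.7	C4H3
ILE	CD1	C	1.87	36.7	C4H3
LEU	N	N	1.65	15.7	N3H1
LEU	CA	C	1.87	13.5	C4H1
LEU	C	C	1.76	9.7	C3H0
LEU	O	O	1.4	15.9	O1H0
LEU	OXT	O	1.4	15.9	O1H0
LEU	CB	C	1.87	23.2	C4H2
LEU	CG	C	1.87	13.5	C4H1
LEU	CD1	C	1.87	36.7	C4H3
LEU	CD2	C	1.87	36.7	C4H3
LYS	N	N	1.65	15.7	N3H1
LYS	CA	C	1.87	13.5	C4H1
LYS	C	C	1.76	9.7	C3H0
LYS	O	O	1.4	15.9	O1H0
LYS	OXT	O	1.4	15.9	O1H0
LYS	CB	C	1.87	23.2	C4H2
LYS	CG	C	1.87	23.2	C4H2
LYS	CD	C	1.87	23.2	C4H2
LYS	CE	C	1.87	23.2	C4H2
LYS	NZ	N	1.65	21.4	N4H3
MET	N	N	1.65	15.7	N3H1
MET	CA	C	1.87	13.5	C4H1
MET	C	C	1.76	9.7	C3H0
MET	O	O	1.4	15.9	O1H0
MET	OXT	O	1.4	15.9	O1H0
MET	CB	C	1.87	23.2	C4H2
MET	CG	C	1.87	23.2	C4H2
MET	SD	S	1.85	29.2	S2H0
MET	CE	C	1.87	36.7	C4H3
PHE	N	N	1.65	15.7	N3H1
PHE	CA	C	1.87	13.5	C4H1
PHE	C	C	1.76	9.7	C3H0
PHE	O	O	1.4	15.9	O1H0
PHE	OXT	O	1.4	15.9	O1H0
PHE	CB	C	1.87	23.2	C4H2
PHE	CG	C	1.76	9.7	C3H0
PHE	CD1	C	1.76	21.3	C3H1
PHE	CD2	C	1.76	21.3	C3H1
PHE	CE1	C	1.76	21.3	C3H1
PHE	CE2	C	1.76	21.3	C3H1
PHE	CZ	C	1.76	21.3	C3H1
PRO	N	N	1.65	8.7	N3H0
PRO	CA	C	1.87	13.5	C4H1
PRO	C	C	1.76	9.7	C3H0
PRO	O	O	1.4	15.9	O1H0
PRO	OXT	O	1.4	15.9	O1H0
PRO	CB	C	1.87	23.2	C4H2
PRO	CG	C	1.87	23.2	C4H2
PRO	CD	C	1.87	23.2	C4H2
SER	N	N	1.65	15.7	N3H1
SER	CA	C	1.87	13.5	C4H1
SER	C	C	1.76	9.7	C3H0
SER	O	O	1.4	15.9	O1H0
SER	OXT	O	1.4	15.9	O1H0
SER	CB	C	1.87	23.2	C4H2
SER	OG	O	1.4	18	O2H1
THR	N	N	1.65	15.7	N3H1
THR	CA	C	1.87	13.5	C4H1
THR	C	C	1.76	9.7	C3H0
THR	O	O	1.4	15.9	O1H0
THR	OXT	O	1.4	15.9	O1H0
THR	CB	C	1.87	13.5	C4H1
THR	OG1	O	1.4	18	O2H1
THR	CG2	C	1.87	36.7	C4H3
TRP	N	N	1.65	15.7	N3H1
TRP	CA	C	1.87	13.5	C4H1
TRP	C	C	1.76	9.7	C3H0
TRP	O	O	1.4	15.9	O1H0
TRP	OXT	O	1.4	15.9	O1H0
TRP	CB	C	1.87	23.2	C4H2
TRP	CG	C	1.76	9.7	C3H0
TRP	CD1	C	1.76	21.3	C3H1
TRP	CD2	C	1.76	9.7	C3H0
TRP	NE1	N	1.65	15.7	N3H1
TRP	CE2	C	1.76	9.7	C3H0
TRP	CE3	C	1.76	21.3	C3H1
TRP	CZ2	C	1.76	21.3	C3H1
TRP	CZ3	C	1.76	21.3	C3H1
TRP	CH2	C	1.76	21.3	C3H1
TYR	N	N	1.65	15.7	N3H1
TYR	CA	C	1.87	13.5	C4H1
TYR	C	C	1.76	9.7	C3H0
TYR	O	O	1.4	15.9	O1H0
TYR	OXT	O	1.4	15.9	O1H0
TYR	CB	C	1.87	23.2	C4H2
TYR	CG	C	1.76	9.7	C3H0
TYR	CD1	C	1.76	21.3	C3H1
TYR	CD2	C	1.76	21.3	C3H1
TYR	CE1	C	1.76	21.3	C3H1
TYR	CE2	C	1.76	21.3	C3H1
TYR	CZ	C	1.76	9.7	C3H0
TYR	OH	O	1.4	18	O2H1
VAL	N	N	1.65	15.7	N3H1
VAL	CA	C	1.87	13.5	C4H1
VAL	C	C	1.76	9.7	C3H0
VAL	O	O	1.4	15.9	O1H0
VAL	OXT	O	1.4	15.9	O1H0
VAL	CB	C	1.87	13.5	C4H1
VAL	CG1	C	1.87	36.7	C4H3
VAL	CG2	C	1.87	36.7	C4H3
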