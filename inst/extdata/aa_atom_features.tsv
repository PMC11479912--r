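residue_name	atom_name	element_code	charge	is_aromatic	in_ring	hybridization_code	explicit_valence	implicit_valence	total_valence
ALA	N	7	0	0	0	2	2	1	3
ALA	CA	6	0	0	0	3	3	1	4
ALA	C	6	0	0	0	2	4	0	4
ALA	O	8	0	0	0	2	2	0	2
ALA	CB	6	0	0	0	3	1	3	4
ARG	N	7	0	0	0	2	2	1	3
ARG	CA	6	0	0	0	3	3	1	4
ARG	C	6	0	0	0	2	4	0	4
ARG	O	8	0	0	0	2	2	0	2
ARG	CB	6	0	0	0	3	2	2	4
ARG	CG	6	0	0	0	3	2	2	4
ARG	CD	6	0	0	0	3	2	2	4
ARG	NE	7	0	0	0	2	2	1	3
ARG	CZ	6	0	0	0	2	4	0	4
ARG	NH1	7	0	0	0	2	2	1	3
ARG	NH2	7	0	0	0	2	1	2	3
ASN	N	7	0	0	0	2	2	1	3
ASN	CA	6	0	0	0	3	3	1	4
ASN	C	6	0	0	0	2	4	0	4
ASN	O	8	0	0	0	2	2	0	2
ASN	CB	6	0	0	0	3	2	2	4
ASN	CG	6	0	0	0	2	4	0	4
ASN	OD1	8	0	0	0	2	2	0	2
ASN	ND2	7	0	0	0	2	1	2	3
ASP	N	7	0	0	0	2	2	1	3
ASP	CA	6	0	0	0	3	3	1	4
ASP	C	6	0	0	0	2	4	0	4
ASP	O	8	0	0	0	2	2	0	2
ASP	CB	6	0	0	0	3	2	2	4
ASP	CG	6	0	0	0	2	4	0	4
ASP	OD1	8	0	0	0	2	2	0	2
ASP	OD2	8	0	0	0	2	1	1	2
CYS	N	7	0	0	0	2	2	1	3
CYS	CA	6	0	0	0	3	3	1	4
CYS	C	6	0	0	0	2	4	0	4
CYS	O	8	0	0	0	2	2	0	2
CYS	CB	6	0	0	0	3	2	2	4
CYS	SG	16	0	0	0	3	1	1	2
GLN	N	7	0	0	0	2	2	1	3
GLN	CA	6	0	0	0	3	3	1	4
GLN	C	6	0	0	0	2	4	0	4
GLN	O	8	0	0	0	2	2	0	2
GLN	CB	6	0	0	0	3	2	2	4
GLN	CG	6	0	0	0	3	2	2	4
GLN	CD	6	0	0	0	2	4	0	4
GLN	OE1	8	0	0	0	2	2	0	2
GLN	NE2	7	0	0	0	2	1	2	3
GLU	N	7	0	0	0	2	2	1	3
GLU	CA	6	0	0	0	3	3	1	4
GLU	C	6	0	0	0	2	4	0	4
GLU	O	8	0	0	0	2	2	0	2
GLU	CB	6	0	0	0	3	2	2	4
GLU	CG	6	0	0	0	3	2	2	4
GLU	CD	6	0	0	0	2	4	0	4
GLU	OE1	8	0	0	0	2	2	0	2
GLU	OE2	8	0	0	0	2	1	1	2
GLY	N	7	0	0	0	2	2	1	3
GLY	CA	6	0	0	0	3	2	2	4
GLY	C	6	0	0	0	2	4	0	4
GLY	O	8	0	0	0	2	2	0	2
HIS	N	7	0	0	0	2	2	1	3
HIS	CA	6	0	0	0	3	3	1	4
HIS	C	6	0	0	0	2	4	0	4
HIS	O	8	0	0	0	2	2	0	2
HIS	CB	6	0	0	0	3	2	2	4
HIS	CG	6	0	1	1	2	4	0	4
HIS	ND1	7	0	1	1	2	3	0	3
HIS	CD2	6	0	1	1	2	3	1	4
HIS	CE1	6	0	1	1	2	3	1	4
HIS	NE2	7	0	1	1	2	3	0	3
ILE	N	7	0	0	0	2	2	1	3
ILE	CA	6	0	0	0	3	3	1	4
ILE	C	6	0	0	0	2	4	0	4
ILE	O	8	0	0	0	2	2	0	2
ILE	CB	6	0	0	0	3	3	1	4
ILE	CG1	6	0	0	0	3	1	3	4
ILE	CG2	6	0	0	0	3	2	2	4
ILE	CD1	6	0	0	0	3	1	3	4
LEU	N	7	0	0	0	2	2	1	3
LEU	CA	6	0	0	0	3	3	1	4
LEU	C	6	0	0	0	2	4	0	4
LEU	O	8	0	0	0	2	2	0	2
LEU	CB	6	0	0	0	3	2	2	4
LEU	CG	6	0	0	0	3	3	1	4
LEU	CD1	6	0	0	0	3	1	3	4
LEU	CD2	6	0	0	0	3	1	3	4
LYS	N	7	0	0	0	2	2	1	3
LYS	CA	6	0	0	0	3	3	1	4
LYS	C	6	0	0	0	2	4	0	4
LYS	O	8	0	0	0	2	2	0	2
LYS	CB	6	0	0	0	3	2	2	4
LYS	CG	6	0	0	0	3	2	2	4
LYS	CD	6	0	0	0	3	2	2	4
LYS	CE	6	0	0	0	3	2	2	4
LYS	NZ	7	0	0	0	3	1	2	3
MET	N	7	0	0	0	2	2	1	3
MET	CA	6	0	0	0	3	3	1	4
MET	C	6	0	0	0	2	4	0	4
MET	O	8	0	0	0	2	2	0	2
MET	CB	6	0	0	0	3	2	2	4
MET	CG	6	0	0	0	3	2	2	4
MET	SD	16	0	0	0	3	2	0	2
MET	CE	6	0	0	0	3	1	3	4
PHE	N	7	0	0	0	2	2	1	3
PHE	CA	6	0	0	0	3	3	1	4
PHE	C	6	0	0	0	2	4	0	4
PHE	O	8	0	0	0	2	2	0	2
PHE	CB	6	0	0	0	3	2	2	4
PHE	CG	6	0	1	1	2	4	0	4
PHE	CD1	6	0	1	1	2	3	1	4
PHE	CD2	6	0	1	1	2	3	1	4
PHE	CE1	6	0	1	1	2	3	1	4
PHE	CE2	6	0	1	1	2	3	1	4
PHE	CZ	6	0	1	1	2	3	1	4
PRO	N	7	0	0	1	2	3	0	3
PRO	CA	6	0	0	1	3	3	1	4
PRO	C	6	0	0	0	2	4	0	4
PRO	O	8	0	0	0	2	2	0	2
PRO	CB	6	0	0	1	3	2	2	4
PRO	CG	6	0	0	1	3	2	2	4
PRO	CD	6	0	0	1	3	2	2	4
SER	N	7	0	0	0	2	2	1	3
SER	CA	6	0	0	0	3	3	1	4
SER	C	6	0	0	0	2	4	0	4
SER	O	8	0	0	0	2	2	0	2
SER	CB	6	0	0	0	3	2	2	4
SER	OG	8	0	0	0	3	1	1	2
THR	N	7	0	0	0	2	2	1	3
THR	CA	6	0	0	0	3	3	1	4
THR	C	6	0	0	0	2	4	0	4
THR	O	8	0	0	0	2	2	0	2
THR	CB	6	0	0	0	3	3	1	4
THR	OG1	8	0	0	0	3	1	1	2
THR	CG2	6	0	0	0	3	1	3	4
TRP	N	7	0	0	0	2	2	1	3
TRP	CA	6	0	0	0	3	3	1	4
TRP	C	6	0	0	0	2	4	0	4
TRP	O	8	0	0	0	2	2	0	2
TRP	CB	6	0	0	0	3	2	2	4
TRP	CG	6	0	1	1	2	4	0	4
TRP	CD1	6	0	1	1	2	3	1	4
TRP	CD2	6	0	1	1	2	4	0	4
TRP	NE1	7	0	1	1	2	3	0	3
TRP	CE2	6	0	1	1	2	4	0	4
TRP	CE3	6	0	1	1	2	3	1	4
TRP	CZ2	6	0	1	1	2	3	1	4
TRP	CZ3	6	0	1	1	2	3	1	4
TRP	CH2	6	0	1	1	2	3	1	4
TYR	N	7	0	0	0	2	2	1	3
TYR	CA	6	0	0	0	3	3	1	4
TYR	C	6	0	0	0	2	4	0	4
TYR	O	8	0	0	0	2	2	0	2
TYR	CB	6	0	0	0	3	2	2	4
TYR	CG	6	0	1	1	2	4	0	4
TYR	CD1	6	0	1	1	2	3	1	4
TYR	CD2	6	0	1	1	2	3	1	4
TYR	CE1	6	0	1	1	2	3	1	4
TYR	CE2	6	0	1	1	2	3	1	4
TYR	CZ	6	0	1	1	2	4	0	4
TYR	OH	8	0	0	0	2	1	1	2
VAL	N	7	0	0	0	2	2	1	3
VAL	CA	6	0	0	0	3	3	1	4
VAL	C	6	0	0	0	2	4	0	4
VAL	O	8	0	0	0	2	2	0	2
VAL	CB	6	0	0	0	3	3	1	4
VAL	CG1	6	0	0	0	3	1	3	4
VAL	CG2	6	0	0	0	3	1	3	4
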