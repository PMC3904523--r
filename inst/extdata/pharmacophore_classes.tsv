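resName	atomName	class
ALA	N	donor
ALA	CA	hydrophobic
ALA	C	neutral
ALA	O	acceptor
ALA	CB	hydrophobic
ARG	N	donor
ARG	CA	hydrophobic
ARG	C	neutral
ARG	O	acceptor
ARG	CB	hydrophobic
ARG	CG	hydrophobic
ARG	CD	hydrophobic
ARG	NE	positive
ARG	CZ	positive
ARG	NH1	positive
ARG	NH2	positive
ASN	N	donor
ASN	CA	hydrophobic
ASN	C	neutral
ASN	O	acceptor
ASN	CB	hydrophobic
ASN	CG	neutral
ASN	OD1	acceptor
ASN	ND2	donor
ASP	N	donor
ASP	CA	hydrophobic
ASP	C	neutral
ASP	O	acceptor
ASP	CB	hydrophobic
ASP	CG	negative
ASP	OD1	negative
ASP	OD2	negative
CYS	N	donor
CYS	CA	hydrophobic
CYS	C	neutral
CYS	O	acceptor
CYS	CB	hydrophobic
CYS	SG	sulphur
GLN	N	donor
GLN	CA	hydrophobic
GLN	C	neutral
GLN	O	acceptor
GLN	CB	hydrophobic
GLN	CG	hydrophobic
GLN	CD	neutral
GLN	OE1	acceptor
GLN	NE2	donor
GLU	N	donor
GLU	CA	hydrophobic
GLU	C	neutral
GLU	O	acceptor
GLU	CB	hydrophobic
GLU	CG	hydrophobic
GLU	CD	negative
GLU	OE1	negative
GLU	OE2	negative
GLY	N	donor
GLY	CA	hydrophobic
GLY	C	neutral
GLY	O	acceptor
HIS	N	donor
HIS	CA	hydrophobic
HIS	C	neutral
HIS	O	acceptor
HIS	CB	hydrophobic
HIS	CG	aromatic
HIS	ND1	aromatic
HIS	CD2	aromatic
HIS	CE1	aromatic
HIS	NE2	aromatic
ILE	N	donor
ILE	CA	hydrophobic
ILE	C	neutral
ILE	O	acceptor
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
LEU	N	donor
LEU	CA	hydrophobic
LEU	C	neutral
LEU	O	acceptor
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	N	donor
LYS	CA	hydrophobic
LYS	C	neutral
LYS	O	acceptor
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
LYS	CE	hydrophobic
LYS	NZ	positive
MET	N	donor
MET	CA	hydrophobic
MET	C	neutral
MET	O	acceptor
MET	CB	hydrophobic
MET	CG	hydrophobic
MET	SD	sulphur
MET	CE	hydrophobic
PHE	N	donor
PHE	CA	hydrophobic
PHE	C	neutral
PHE	O	acceptor
PHE	CB	hydrophobic
PHE	CG	aromatic
PHE	CD1	aromatic
PHE	CD2	aromatic
PHE	CE1	aromatic
PHE	CE2	aromatic
PHE	CZ	aromatic
PRO	N	neutral
PRO	CA	hydrophobic
PRO	C	neutral
PRO	O	acceptor
PRO	CB	hydrophobic
PRO	CG	hydrophobic
PRO	CD	hydrophobic
SER	N	donor
SER	CA	hydrophobic
SER	C	neutral
SER	O	acceptor
SER	CB	hydrophobic
SER	OG	donor
THR	N	donor
THR	CA	hydrophobic
THR	C	neutral
THR	O	acceptor
THR	CB	hydrophobic
THR	OG1	donor
THR	CG2	hydrophobic
TRP	N	donor
TRP	CA	hydrophobic
TRP	C	neutral
TRP	O	acceptor
TRP	CB	hydrophobic
TRP	CG	aromatic
TRP	CD1	aromatic
TRP	CD2	aromatic
TRP	NE1	aromatic
TRP	CE2	aromatic
TRP	CE3	aromatic
TRP	CZ2	aromatic
TRP	CZ3	aromatic
TRP	CH2	aromatic
TYR	N	donor
TYR	CA	hydrophobic
TYR	C	neutral
TYR	O	acceptor
TYR	CB	hydrophobic
TYR	CG	aromatic
TYR	CD1	aromatic
TYR	CD2	aromatic
TYR	CE1	aromatic
TYR	CE2	aromatic
TYR	CZ	aromatic
TYR	OH	donor
VAL	N	donor
VAL	CA	hydrophobic
VAL	C	neutral
VAL	O	acceptor
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
ALA	OXT	negative
ARG	OXT	negative
ASN	OXT	negative
ASP	OXT	negative
CYS	OXT	negative
GLN	OXT	negative
GLU	OXT	negative
GLY	OXT	negative
HIS	OXT	negative
ILE	OXT	negative
LEU	OXT	negative
LYS	OXT	negative
MET	OXT	negative
PHE	OXT	negative
PRO	OXT	negative
SER	OXT	negative
THR	OXT	negative
TRP	OXT	negative
TYR	OXT	negative
VAL	OXT	negative
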