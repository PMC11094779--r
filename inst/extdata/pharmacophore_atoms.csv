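# Pharmacophore class assignment for heavy atoms of the 20 standard amino acids.
# Classes: hydrophobic, positive, negative, acceptor, donor, aromatic, sulfur, neutral.
# Rules: hydrophobic = carbon bonded only to C/H; aromatic ring atoms get 'aromatic'
# (ring carbons bonded only to C/H are also hydrophobic); charged groups at pH 7;
# amide/hydroxyl/imidazole N,O get donor/acceptor per standard H-bond chemistry.
# 'SC' rows are single side-chain pseudo-atoms (union of the residue's side-chain
# classes) used by the synthetic helical-bundle generator; they are excluded from
# residue template tallies, as is the optional terminal OXT.
# version: 1
res_name,atom_name,classes
ALA,N,donor
ALA,CA,neutral
ALA,C,neutral
ALA,O,acceptor
ALA,OXT,acceptor
ALA,CB,hydrophobic
ALA,SC,hydrophobic
ARG,N,donor
ARG,CA,neutral
ARG,C,neutral
ARG,O,acceptor
ARG,OXT,acceptor
ARG,CB,hydrophobic
ARG,CG,hydrophobic
ARG,CD,neutral
ARG,NE,positive;donor
ARG,CZ,positive
ARG,NH1,positive;donor
ARG,NH2,positive;donor
ARG,SC,hydrophobic;neutral;positive;donor
ASN,N,donor
ASN,CA,neutral
ASN,C,neutral
ASN,O,acceptor
ASN,OXT,acceptor
ASN,CB,hydrophobic
ASN,CG,neutral
ASN,OD1,acceptor
ASN,ND2,donor
ASN,SC,hydrophobic;neutral;acceptor;donor
ASP,N,donor
ASP,CA,neutral
ASP,C,neutral
ASP,O,acceptor
ASP,OXT,acceptor
ASP,CB,hydrophobic
ASP,CG,neutral
ASP,OD1,negative;acceptor
ASP,OD2,negative;acceptor
ASP,SC,hydrophobic;neutral;negative;acceptor
CYS,N,donor
CYS,CA,neutral
CYS,C,neutral
CYS,O,acceptor
CYS,OXT,acceptor
CYS,CB,neutral
CYS,SG,sulfur
CYS,SC,neutral;sulfur
GLN,N,donor
GLN,CA,neutral
GLN,C,neutral
GLN,O,acceptor
GLN,OXT,acceptor
GLN,CB,hydrophobic
GLN,CG,hydrophobic
GLN,CD,neutral
GLN,OE1,acceptor
GLN,NE2,donor
GLN,SC,hydrophobic;neutral;acceptor;donor
GLU,N,donor
GLU,CA,neutral
GLU,C,neutral
GLU,O,acceptor
GLU,OXT,acceptor
GLU,CB,hydrophobic
GLU,CG,hydrophobic
GLU,CD,neutral
GLU,OE1,negative;acceptor
GLU,OE2,negative;acceptor
GLU,SC,hydrophobic;neutral;negative;acceptor
GLY,N,donor
GLY,CA,neutral
GLY,C,neutral
GLY,O,acceptor
GLY,OXT,acceptor
HIS,N,donor
HIS,CA,neutral
HIS,C,neutral
HIS,O,acceptor
HIS,OXT,acceptor
HIS,CB,hydrophobic
HIS,CG,aromatic
HIS,ND1,aromatic;acceptor
HIS,CD2,aromatic
HIS,CE1,aromatic
HIS,NE2,aromatic;donor
HIS,SC,hydrophobic;aromatic;acceptor;donor
ILE,N,donor
ILE,CA,neutral
ILE,C,neutral
ILE,O,acceptor
ILE,OXT,acceptor
ILE,CB,hydrophobic
ILE,CG1,hydrophobic
ILE,CG2,hydrophobic
ILE,CD1,hydrophobic
ILE,SC,hydrophobic
LEU,N,donor
LEU,CA,neutral
LEU,C,neutral
LEU,O,acceptor
LEU,OXT,acceptor
LEU,CB,hydrophobic
LEU,CG,hydrophobic
LEU,CD1,hydrophobic
LEU,CD2,hydrophobic
LEU,SC,hydrophobic
LYS,N,donor
LYS,CA,neutral
LYS,C,neutral
LYS,O,acceptor
LYS,OXT,acceptor
LYS,CB,hydrophobic
LYS,CG,hydrophobic
LYS,CD,hydrophobic
LYS,CE,neutral
LYS,NZ,positive;donor
LYS,SC,hydrophobic;neutral;positive;donor
MET,N,donor
MET,CA,neutral
MET,C,neutral
MET,O,acceptor
MET,OXT,acceptor
MET,CB,hydrophobic
MET,CG,neutral
MET,SD,sulfur
MET,CE,neutral
MET,SC,hydrophobic;neutral;sulfur
PHE,N,donor
PHE,CA,neutral
PHE,C,neutral
PHE,O,acceptor
PHE,OXT,acceptor
PHE,CB,hydrophobic
PHE,CG,aromatic;hydrophobic
PHE,CD1,aromatic;hydrophobic
PHE,CD2,aromatic;hydrophobic
PHE,CE1,aromatic;hydrophobic
PHE,CE2,aromatic;hydrophobic
PHE,CZ,aromatic;hydrophobic
PHE,SC,hydrophobic;aromatic
PRO,N,neutral
PRO,CA,neutral
PRO,C,neutral
PRO,O,acceptor
PRO,OXT,acceptor
PRO,CB,hydrophobic
PRO,CG,hydrophobic
PRO,CD,neutral
PRO,SC,hydrophobic;neutral
SER,N,donor
SER,CA,neutral
SER,C,neutral
SER,O,acceptor
SER,OXT,acceptor
SER,CB,neutral
SER,OG,acceptor;donor
SER,SC,neutral;acceptor;donor
THR,N,donor
THR,CA,neutral
THR,C,neutral
THR,O,acceptor
THR,OXT,acceptor
THR,CB,neutral
THR,OG1,acceptor;donor
THR,CG2,hydrophobic
THR,SC,neutral;acceptor;donor;hydrophobic
TRP,N,donor
TRP,CA,neutral
TRP,C,neutral
TRP,O,acceptor
TRP,OXT,acceptor
TRP,CB,hydrophobic
TRP,CG,aromatic;hydrophobic
TRP,CD1,aromatic
TRP,CD2,aromatic;hydrophobic
TRP,NE1,aromatic;donor
TRP,CE2,aromatic
TRP,CE3,aromatic;hydrophobic
TRP,CZ2,aromatic;hydrophobic
TRP,CZ3,aromatic;hydrophobic
TRP,CH2,aromatic;hydrophobic
TRP,SC,hydrophobic;aromatic;donor
TYR,N,donor
TYR,CA,neutral
TYR,C,neutral
TYR,O,acceptor
TYR,OXT,acceptor
TYR,CB,hydrophobic
TYR,CG,aromatic;hydrophobic
TYR,CD1,aromatic;hydrophobic
TYR,CD2,aromatic;hydrophobic
TYR,CE1,aromatic;hydrophobic
TYR,CE2,aromatic;hydrophobic
TYR,CZ,aromatic
TYR,OH,acceptor;donor
TYR,SC,hydrophobic;aromatic;acceptor;donor
VAL,N,donor
VAL,CA,neutral
VAL,C,neutral
VAL,O,acceptor
VAL,OXT,acceptor
VAL,CB,hydrophobic
VAL,CG1,hydrophobic
VAL,CG2,hydrophobic
VAL,SC,hydrophobic
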