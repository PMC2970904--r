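# synthetic stand-in for a helix chi1 rotamer reference table
# (three-state populations per residue type; not survey data)
residue_type,p,m,t
ARG,0.05,0.70,0.25
ASN,0.08,0.77,0.15
ASP,0.09,0.76,0.15
CYS,0.07,0.71,0.22
GLN,0.05,0.72,0.23
GLU,0.05,0.71,0.24
HIS,0.08,0.72,0.20
ILE,0.04,0.73,0.23
LEU,0.02,0.66,0.32
LYS,0.05,0.70,0.25
MET,0.06,0.68,0.26
PHE,0.05,0.73,0.22
SER,0.33,0.52,0.15
THR,0.40,0.49,0.11
TRP,0.07,0.72,0.21
TYR,0.06,0.73,0.21
VAL,0.08,0.20,0.72
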