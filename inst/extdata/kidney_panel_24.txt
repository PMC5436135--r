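TP53
VHL
PBRM1
SETD2
KDM5C
BAP1
NF2
PTEN
ARID1A
MICALCL
STAG2
SLC1A3
CDKN1A
MTOR
MET
SMARCB1
TCEB1
NFE2L2
PIK3CA
MLL3
FH
FLCN
TSC1
TSC2
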