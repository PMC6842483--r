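MYC
KRAS
EGFR
ERBB2
MDM2
CCND1
CDK4
CDK9
AKT1
AKT2
PIK3CA
BRAF
NRAS
HRAS
MYCN
MYCL
ABL1
ALK
MET
FGFR1
FGFR2
FGFR3
IGF1R
KIT
PDGFRA
RET
SRC
JUN
FOS
NOTCH1
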