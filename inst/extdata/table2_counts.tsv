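gene	n_AU	n_DD
PRAME	19	0
NPM1	40	0
SOX2	303	0
NFASC	44	0
MYCN	24	0
EHF	24	0
FAM60A	96	0
CD274	48	0
FGFR1	113	0
STK11	12	33
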