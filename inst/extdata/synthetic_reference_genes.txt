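CANDG1
CANDG2
KCNQ3
UBE2H
HCN1
XKR6
ZNF107
EHMT2
CASP1
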