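# Genes shared by the AD-psychosis combined network and the Vitamin D network
CACNA1C
COMT
NOTCH4
DRD3
CD36
EGR1
CCL2
DLX5
CYP1A1
A2M
VDR
TGFB2
TIMP3
CD14
CYP19A1
NME1
HSD11B1
MMP12
AMBRA1
ALOX15
GIG25
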