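gene	weight
CDH1	0.825
EPCAM	0.936
CLDN3	0.631
CLDN4	0.302
CLDN7	0.668
CRB3	0.963
DSP	0.501
ESRP1	0.922
ESRP2	0.522
GRHL2	0.827
KRT8	0.757
KRT18	1.088
KRT19	1.143
OCLN	1.061
MARVELD3	0.509
RAB25	0.768
ST14	0.526
SPINT1	0.473
SPINT2	0.705
TJP3	1.025
F11R	0.483
CDS1	0.804
AP1M2	0.793
MAP7	1.067
MYO5C	0.322
EPN3	1.128
GALNT3	0.232
PRSS8	0.687
TMEM30B	0.6
C1orf116	0.371
ERBB3	0.382
IRF6	0.424
EHF	0.959
ELF3	1.175
FOXA1	0.69
GRHL1	0.9
OVOL2	0.691
MPZL2	0.644
VIM	-0.619
ZEB1	-0.514
ZEB2	-0.396
SNAI1	-0.958
SNAI2	-0.778
TWIST1	-1.113
TWIST2	-1.019
CDH2	-1.082
FN1	-0.988
FOXC2	-0.77
MMP2	-0.744
MMP9	-0.387
SPARC	-0.715
TNC	-0.49
VCAN	-0.241
POSTN	-0.865
COL1A1	-1.092
COL1A2	-1.098
COL3A1	-0.907
COL5A2	-0.609
THBS1	-0.999
SERPINE1	-1.167
TGFB1	-0.97
TGFBI	-0.203
WNT5A	-0.744
ITGB1	-0.536
ITGA5	-0.692
AXL	-0.234
FAP	-0.358
PDGFRB	-0.837
S100A4	-1.007
SULF1	-1.024
EMP3	-0.696
GEM	-0.671
CMTM3	-0.763
DKK1	-0.436
PCOLCE	-0.426
LOXL2	-1.086
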