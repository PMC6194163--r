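AARS2
ACAD8
AMACR
ATPAF2
C10orf2
C12ORF65
CLPP
COQ7
COX10
DNA2
FBXL4
KARS
MFN2
MRPL44
MTFMT
MTO1
NDUFA12
NDUFAF4
NDUFAF5
NDUFS1
NDUFS7
NDUFV2
OPA1
POLG1
PYCR2
QRSL1
SDHA
SERAC1
SLC25A32
SLC25A46
SPG7
SURF1
TIMM22
TMEM126A
TMEM126B
TRMU
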