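ACTA1
BICD2
C10orf2
CASK
CTNNB1
DNA2
DYNC1H1
KIF1A
MFN2
OPA1
PURA
SCN2A
TUBB4A
WDR45
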