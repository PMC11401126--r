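AKT1
NFKB1
CTNNB1
EGFR
MMP1
MMP9
CD44
STAT3
IFNG
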