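source	target	effect	disease
EGFR	AKT1	activate	T2DM
CD44	AKT1	activate	T2DM
AKT1	NFKB1	activate	T2DM
AKT1	STAT3	activate	T2DM
AKT1	MMP9	activate	T2DM
NFKB1	MMP9	activate	T2DM
STAT3	MMP1	activate	T2DM
CTNNB1	MMP1	activate	T2DM
CTNNB1	MMP9	activate	T2DM
EGFR	AKT1	activate	OA
CD44	AKT1	activate	OA
AKT1	NFKB1	activate	OA
AKT1	STAT3	activate	OA
AKT1	MMP9	activate	OA
NFKB1	MMP9	activate	OA
STAT3	MMP1	activate	OA
CTNNB1	MMP1	activate	OA
CTNNB1	MMP9	activate	OA
EGFR	AKT1	activate	TNBC
CD44	AKT1	activate	TNBC
AKT1	NFKB1	activate	TNBC
AKT1	STAT3	activate	TNBC
AKT1	MMP9	activate	TNBC
NFKB1	MMP9	activate	TNBC
STAT3	MMP1	activate	TNBC
CTNNB1	MMP1	activate	TNBC
CTNNB1	MMP9	activate	TNBC
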