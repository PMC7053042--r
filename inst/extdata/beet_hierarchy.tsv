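pool_id	accession	crop_type	species
EL10	EL10	sugar	Beta vulgaris
C869	C869	sugar	Beta vulgaris
EL50	EL50	sugar	Beta vulgaris
EL51	EL51	sugar	Beta vulgaris
GP10	GP10	sugar	Beta vulgaris
GP9	GP9	sugar	Beta vulgaris
L19	L19	sugar	Beta vulgaris
SP7322	SP7322	sugar	Beta vulgaris
SR102	SR102	sugar	Beta vulgaris
SR98	SR98	sugar	Beta vulgaris
BBTB	BBTB	table	Beta vulgaris
Crosby	Crosby	table	Beta vulgaris
DDRT	DDRT	table	Beta vulgaris
RQ	RQ	table	Beta vulgaris
TG	TG	table	Beta vulgaris
W357B	W357B	table	Beta vulgaris
WT	WT	table	Beta vulgaris
MAM	MAM	fodder	Beta vulgaris
WGF	WGF	fodder	Beta vulgaris
FGSC	FGSC	chard	Beta vulgaris
LUC	LUC	chard	Beta vulgaris
RHU	RHU	chard	Beta vulgaris
Vulcan	Vulcan	chard	Beta vulgaris
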