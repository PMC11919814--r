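class_code	synonyms	category	backbone_chains	ether_ok	sphingoid
TAG	TG	GL	3	FALSE	FALSE
DAG	DG	GL	2	FALSE	FALSE
MG	MAG	GL	1	FALSE	FALSE
PC		GP	2	TRUE	FALSE
PE		GP	2	TRUE	FALSE
PS		GP	2	FALSE	FALSE
PI		GP	2	FALSE	FALSE
PG		GP	2	FALSE	FALSE
PA		GP	2	FALSE	FALSE
LPC	LysoPC	GP	1	TRUE	FALSE
LPE	LysoPE	GP	1	TRUE	FALSE
LPS	LysoPS	GP	1	FALSE	FALSE
LPI	LysoPI	GP	1	FALSE	FALSE
LPG	LysoPG	GP	1	FALSE	FALSE
LPA	LysoPA	GP	1	FALSE	FALSE
SM		SP	2	FALSE	TRUE
Cer	CER	SP	2	FALSE	TRUE
HexCer	GlcCer,GalCer	SP	2	FALSE	TRUE
CE	ChE,CholesterylEster	ST	1	FALSE	FALSE
FA	FFA	FA	1	FALSE	FALSE
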