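label	parent	motif
SA	NA	201:T
SA1'2	SA	201:T;202:C
SA1	SA1'2	201:T;202:C;203:G
SA1a	SA1	201:T;202:C;203:G;16066:A
SA1a1	SA1a	201:T;202:C;203:G;16066:A;205:T
SA1a2	SA1a	201:T;202:C;203:G;16066:A;206:C
SA1a3	SA1a	201:T;202:C;203:G;16066:A;207:G
SA2	SA1'2	201:T;202:C;208:A
SA3	SA	201:T;209:T
SE	NA	301:G
SB	NA	401:C
SB1	SB	401:C;402:T
SB1a	SB1	401:C;402:T;403:A
SB1a1	SB1a	401:C;402:T;403:A;404:G
SB1a2	SB1a	401:C;402:T;403:A;405:C
SB1b	SB1	401:C;402:T;406:T
SB2'3'4	SB	401:C;407:A
SB2	SB2'3'4	401:C;407:A;408:G
SB2a	SB2	401:C;407:A;408:G;409:C
SB2b	SB2	401:C;407:A;408:G;410:T
SB3	SB2'3'4	401:C;407:A;411:A
SB3a	SB3	401:C;407:A;411:A;412:G
SB3a1	SB3a	401:C;407:A;411:A;412:G;413:C
SB4	SB2'3'4	401:C;407:A;414:T
SC	NA	501:A
SD	NA	601:G
SD1	SD	601:G;602:C
SD2	SD	601:G;603:T
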