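source_name	source_class	node	sign	original_value	destination_name	destination_class	destination_context	destination_states	n_entry_states
M0/M2c/M2c/M0	cycle	STAT1	+	0	M1	pure fixed point	STAT1=1	10000100000001000	4
M0/M2c/M2c/M0	cycle	STAT3	-	varies	M0	pure fixed point	STAT3=0	00000000000001000	4
M0/M2c/M2c/M0	cycle	STAT3	+	varies	M2c	pure fixed point	STAT3=1	01000100000001000	4
M0/M2c/M2c/M0	cycle	STAT6	+	0	M2a/M2aM2c/M2aM2c/M2a	cycle	STAT6=1	00100000000001000/01100000000001000/01100100000001000/00100100000001000	4
M0/M2c/M2c/M0	cycle	NFKB	+	0	M1	pure fixed point	NFKB=1	00010100000001000	4
M0/M2c/M2c/M0	cycle	AP1	+	0	M2b/M2bM2c/M2bM2c/M2b	cycle	AP1=1	00001000000001000/01001000000001000/01001100000001000/00001100000001000	4
M0/M2c/M2c/M0	cycle	SOCS3	-	varies	M2c	pure fixed point	SOCS3=0	01000000000001000	4
M0/M2c/M2c/M0	cycle	SOCS3	+	varies	M0	pure fixed point	SOCS3=1	00000100000001000	4
M0/M2c/M2c/M0	cycle	PPARG	+	0	M2a/M2aM2c/M2aM2c/M2a	cycle	PPARG=1	00100010000001000/01100010000001000/01100110000001000/00100110000001000	4
M0/M2c/M2c/M0	cycle	KLF4	+	0	M2a/M2aM2c/M2aM2c/M2a	cycle	KLF4=1	00100001000001000/01100001000001000/01100101000001000/00100101000001000	4
M0/M2c/M2c/M0	cycle	HIF1A	+	0	M2aM2d/M2aM2cM2d/M2aM2cM2d/M2aM2d	cycle	HIF1A=1	00100011100001000/01100011100001000/01100111100001000/00100111100001000	4
M0/M2c/M2c/M0	cycle	IFNG	+	0	M1	pure fixed point	IFNG=1	10000100010001000	4
M0/M2c/M2c/M0	cycle	GMCSF	+	0	M1	pure fixed point	GMCSF=1	00010100001001000	4
M0/M2c/M2c/M0	cycle	IL4	+	0	M2a/M2aM2c/M2aM2c/M2a	cycle	IL4=1	00100000000101000/01100000000101000/01100100000101000/00100100000101000	4
M0/M2c/M2c/M0	cycle	IL6	+	0	M2b/M2bM2c/M2bM2c/M2b	cycle	IL6=1	00001000000011000/01001000000011000/01001100000011000/00001100000011000	4
M0/M2c/M2c/M0	cycle	IL10	-	1	M0	pure fixed point	IL10=0	00000000000000000	4
M0/M2c/M2c/M0	cycle	IL1B	+	0	M1M2b	hybrid fixed point	IL1B=1	00011100000001100	4
M0/M2c/M2c/M0	cycle	TNFA	+	0	M1	pure fixed point	TNFA=1	00010100000001010	4
M0/M2c/M2c/M0	cycle	TGFB	+	0	M0/M2c/M2c/M0	cycle	TGFB=1	00000000000001001/01000000000001001/01000100000001001/00000100000001001	4
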