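source_name	source_class	node	sign	original_value	destination_name	destination_class	destination_context	destination_states	n_entry_states
M1	pure fixed point	STAT1	-	1	M1	pure fixed point	STAT1=0	00010100011000010	1
M1	pure fixed point	STAT3	+	0	M1M2c	hybrid fixed point	STAT3=1	11010100011000010	1
M1	pure fixed point	STAT6	+	0	M2a	pure fixed point	STAT6=1	00100000011000010	1
M1	pure fixed point	NFKB	-	1	M1	pure fixed point	NFKB=0	10000100011000010	1
M1	pure fixed point	AP1	+	0	M1M2b	hybrid fixed point	AP1=1	10011100011000010	1
M1	pure fixed point	SOCS3	-	1	M1	pure fixed point	SOCS3=0	10010000011000010	1
M1	pure fixed point	PPARG	+	0	M2a	pure fixed point	PPARG=1	00100010011000010	1
M1	pure fixed point	KLF4	+	0	M2a	pure fixed point	KLF4=1	00100001011000010	1
M1	pure fixed point	HIF1A	+	0	M2aM2d	hybrid fixed point	HIF1A=1	00100011111000010	1
M1	pure fixed point	IFNG	-	1	M1	pure fixed point	IFNG=0	00010100001000010	1
M1	pure fixed point	GMCSF	-	1	M1	pure fixed point	GMCSF=0	10010100010000010	1
M1	pure fixed point	IL4	+	0	M2a	pure fixed point	IL4=1	00100000011100010	1
M1	pure fixed point	IL6	+	0	M1M2b	hybrid fixed point	IL6=1	10011100011010010	1
M1	pure fixed point	IL10	+	0	M1	pure fixed point	IL10=1	10010100011001010	1
M1	pure fixed point	IL1B	+	0	M1M2b	hybrid fixed point	IL1B=1	10011100011000110	1
M1	pure fixed point	TNFA	-	1	M1	pure fixed point	TNFA=0	10010100011000000	1
M1	pure fixed point	TGFB	+	0	M1	pure fixed point	TGFB=1	10010100011000011	1
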