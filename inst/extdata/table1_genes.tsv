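call_id	symbol
c01	ZNF595
c01	ZNF718
c01	ZNF876P
c01	ZNF732
c01	ZNF141
c01	ABCA11P
c01	ZNF721
c01	PIGG
c01	PDE6B
c01	ATP5I
c01	MYL5
c01	MFSD7
c01	PCGF3
c01	LOC100129917
c01	CPLX1
c01	GAK
c01	TMEM175
c01	DGKQ
c01	SLC26A1
c01	IDUA
c01	FGFRL1
c01	RNF212
c01	TMED11P
c01	SPON2
c01	LOC100130872
c01	CTBP1
c01	CTBP1-AS1
c01	MAEA
c01	UVSSA
c01	CRIPAK
c01	FAM53A
c01	SLBP
c01	TMEM129
c01	TACC3
c01	FGFR3
c01	LETM1
c02	EPHA5
c02	LOC100144602
c03	ABCG2
c03	PPM1K
c03	HERC6
c03	HERC5
c03	PIGY
c03	HERC3
c03	NAP1L5
c03	FAM13A-AS1
c03	FAM13A
c03	TIGD2
c03	GPRIN3
c04	ZNF488
c04	RBP3
c04	GDF2
c04	GDF10
c04	PTPN20A
c04	PTPN20B
c04	FRMPD2P1
c04	BMS1P1
c04	BMS1P5
c04	GLUD1P7
c04	FAM25B
c04	FAM25C
c04	FAM25G
c04	LOC399753
c04	FRMPD2
c04	MAPK8
c04	ARHGAP22
c04	WDFY4
c04	LRRC18
c04	MIR4294
c04	VSTM4
c04	LOC100506733
c04	FAM170B
c04	C10orf128
c04	C10orf71
c04	DRGX
c04	ERCC6
c04	PGBD3
c04	CHAT
c04	SLC18A3
c04	C10orf53
c04	OGDHL
c04	PARG
c04	AGAP8
c04	LOC728407
c04	AGAP7
c04	MSMB
c04	NCOA4
c04	TIMM23
c04	AGAP6
c04	FLJ31813
c04	FAM21A
c05	LRRTM3
c06	ADK
c07	TRIM34
c07	TRIM6-TRIM34
c07	TRIM5
c07	TRIM22
c07	OR56B1
c07	OR52N4
c07	OR52N5
c07	OR52N1
c07	OR52N2
c07	OR52E6
c07	OR52E8
c07	OR52E4
c07	OR56A3
c07	OR56A5
c07	OR52L1
c07	OR56A4
c07	OR56A1
c07	OR56B4
c07	OR52B2
c07	OR52W1
c07	C11orf42
c07	FAM160A2
c07	CNGA4
c07	CCKBR
c07	PRKCDBP
c07	SMPD1
c07	APBB1
c07	HPX
c07	TRIM3
c07	ARFIP2
c07	FXC1
c07	DNHD1
c07	RRP8
c07	ILK
c07	TAF10
c07	TPP1
c07	DCHS1
c07	MRPL17
c07	GVINP1
c07	OR2AG2
c07	OR2AG1
c07	OR6A2
c07	OR10A5
c07	OR10A2
c07	OR10A4
c07	OR2D2
c07	OR2D3
c07	ZNF215
c07	ZNF214
c07	NLRP14
c07	RBMXL2
c07	SYT9
c08	WHAMMP2
c08	LOC100289656
c08	LOC646278
c08	GOLGA6L7P
c08	APBA2
c08	FAM189A1
c08	NDNL2
c08	TJP1
c09	TM2D3
c09	TARSL2
c09	OR4F6
c09	OR4F15
c09	OR4F13P
c10	RBFOX1
c11	MPV17L
c11	C16orf45
c11	KIAA0430
c11	NDE1
c11	MIR484
c11	MYH11
c11	FOPNL
c11	ABCC1
c11	ABCC6
c12	UQCRC2
c12	PDZD9
c12	C16orf52
c12	VWA3A
c12	EEF2K
c12	POLR3E
c12	CDR2
c13	UBOX5
c13	UBOX5-AS1
c13	FASTKD5
c13	PROSAPIP1
c13	DDRGK1
c13	ITPA
c13	SLC4A11
c13	C20orf194
c13	ATRN
c13	GFRA4
c13	ADAM33
c13	SIGLEC1
c13	HSPA12B
c13	C20orf27
c13	SPEF1
c13	CENPB
c13	CDC25B
c13	AP5S1
c13	MAVS
c13	PANK2
c14	DGCR6
c14	PRODH
c14	DGCR5
c14	DGCR9
c14	DGCR10
c14	DGCR2
c14	DGCR11
c14	DGCR14
c14	TSSK2
c14	GSC2
c14	SLC25A1
c14	CLTCL1
c14	HIRA
c14	MRPL40
c14	C22orf39
c14	UFD1L
c14	CDC45
c14	CLDN5
c14	LOC150185
c14	Sep-05
c14	SEPT5-GP1BB
c14	GP1BB
c14	TBX1
c14	GNB1L
c14	C22orf29
c14	TXNRD2
c14	COMT
c14	MIR4761
c14	ARVCF
c14	C22orf25
c14	MIR185
c14	DGCR8
c14	MIR3618
c14	MIR1306
c14	TRMT2A
c14	RANBP1
c14	ZDHHC8
c14	LOC388849
c14	LOC284865
c14	LOC150197
c14	RTN4R
c14	MIR1286
c14	DGCR6L
c14	LOC729444
c14	TMEM191B
c14	PI4KAP1
c14	RIMBP3
c14	ZNF74
c14	SCARF2
c14	KLHL22
c14	MED15
c14	POM121L4P
c14	TMEM191A
c14	PI4KA
c14	SERPIND1
c14	SNAP29
c14	CRKL
c14	AIFM3
c14	LZTR1
c14	THAP7
c14	THAP7-AS1
c14	TUBA3FP
c14	P2RX6
c14	SLC7A4
c14	P2RX6P
c14	LOC400891
c14	BCRP2
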