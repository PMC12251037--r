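chr1	1000000	1050000	MTHFR
chr2	2000000	2050000	DHFR
chr3	3000000	3050000	MTHFD1
chr4	4000000	4050000	MTHFD1L
chr5	5000000	5050000	SHMT1
chr6	6000000	6050000	SHMT2
chr7	7000000	7050000	TYMS
chr8	8000000	8050000	ALDH1L1
chr9	9000000	9050000	FPGS
chr10	10000000	10050000	GART
chr11	11000000	11050000	FOLR1
chr12	12000000	12050000	FOLR2
chr13	13000000	13050000	FOLR3
chr14	14000000	14050000	SLC19A1
chr15	15000000	15050000	SLC46A1
chr16	16000000	16050000	TCN1
chr17	17000000	17050000	TCN2
chr18	18000000	18050000	CUBN
chr19	19000000	19050000	MTR
chr20	20000000	20050000	MTRR
chr21	21000000	21050000	MAT1A
chr22	22000000	22050000	MAT2A
chr1	23000000	23050000	MAT2B
chr2	24000000	24050000	AHCY
chr3	25000000	25050000	BHMT
chr4	26000000	26050000	BHMT2
chr5	27000000	27050000	GNMT
chr6	28000000	28050000	AMD1
chr7	29000000	29050000	DNMT1
chr8	30000000	30050000	DNMT3A
chr9	31000000	31050000	DNMT3B
chr10	32000000	32050000	PEMT
chr11	33000000	33050000	CBS
chr12	34000000	34050000	CTH
chr13	35000000	35050000	PRMT3
chr14	36000000	36050000	CHAT
chr15	37000000	37050000	PLD2
chr16	38000000	38050000	TBC1D1
chr17	39000000	39050000	DTHD1
chr18	40000000	40050000	CCT3
chr19	41000000	41050000	HIF3A
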