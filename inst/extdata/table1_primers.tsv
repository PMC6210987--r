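Gene	Primer Name	Role	Sequence	Annealing
BMX	BMX-F1	F1	GAACTTACATACAGATCGTC	55
BMX	BMX-F3	F3	GAACTTACATACAGATCGTT	55
BMX	BMX-R	R	CTTCCAACCCAAGCCATTAC	55
FAM208B	FAM208B-F1	F1	CCACTCCTTGGTGGAGTATT	55
FAM208B	FAM208B-F3	F3	CCACTCCTTGGTGGAGTATC	55
FAM208B	FAM208B-R	R	AGAAAGATGAGGATCGTGCG	55
IFT140	IFT140-F1	F1	AAATCCATCAAGTTGATTAA	55
IFT140	IFT140-F3	F3	AAATCCATCAAGTTGATTAG	55
IFT140	IFT140-R	R	TCTTTCTGAGAACGAAAGGG	55
IGSF	IGSF-F1	F1	CAATGGGACTGTGCTGAGTC	63
IGSF	IGSF-F2	F3	CAATGGGACTGTGCTGAGTT	63
IGSF	IGSF-R	R	TCTCAGGCAGAGGTGATGAT	63
LAMB4	LAMB4-F1	F1	TCTCTTATTTGCGTTCAATT	55
LAMB4	LAMB4-F3	F3	TCTCTTATTTGCGTTCAATC	55
LAMB4	LAMB4-R	R	TTGCAGATGAGAGTGTGCCT	55
PIK3R4	PIK3R4-F1	F1	ACTAGGGTGAGATGTTTAAT	55
PIK3R4	PIK3R4-F3	F3	ACTAGGGTGAGATGTTTAAC	55
PIK3R4	PIK3R4-R	R	GGGGATCATCAGAAGTCTGT	55
THADA	THADA-F1	F1	ACAAACCATGCTGGCATACT	63
THADA	THADA-F3	F3	ACAAACCATGCTGGCATACC	63
THADA	THADA-R	R	CAGGACATGCTAACCTCTGT	63
TOPAZ1	TOPAZ1-F1	F1	AAGCTCTGGTAGGCTACGGG	63
TOPAZ1	TOPAZ1-F3	F3	AAGCTCTGGTAGGCTACGGT	63
TOPAZ1	TOPAZ1-R	R	CAGGCCAGAATACTGCATCT	63
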