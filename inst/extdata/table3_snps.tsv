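Contig ID	C	Ref Pos	Ref Base	Called Base	Impact	SNP%	Feature Name	DNA Change	AA Change	Depth	A Cnt	C Cnt	G Cnt	T Cnt	Del
NC_006088	1	1034107	T	C	N-syn	1	FAM208B	c.4777A>G	p.K1593E	13	0	13	0	-	0
NC_006088	1	14729572	T	C	N-syn	0.8	LAMB4	c.4640A>G	p.K1547R	10	0	8	0	-	0
NC_006088	1	64181733	G	T	N-syn	1	PIK3C2G	c.1585G>T	p.A529S	10	0	0	-	10	0
NC_006088	1	65873551	C	G	N-syn	0.9	LOC101748372	c.960G>C	p.R320S	11	0	-	10	0	0
NC_006088	1	104629701	G	A	N-syn	1	IFNAR2	c.1099G>A	p.A367T	11	11	0	-	0	0
NC_006088	1	112303547	A	C	N-syn	0.8	RPGR	c.2209A>C	p.I737L	10	-	8	0	0	0
NC_006088	1	121349181	C	T|C	N-syn	0.75	BMX	c.[1549G>G]+[1549G>A]	p.D517N, p.D517D	12	0	-	0	9	0
NC_006088	1	127837266	G	T	N-syn	0.89	ARSD	c.449G>T	p.W150L	10	0	0	-	9	0
NC_006088	1	179358329	A	T|A	N-syn	0.76	DDX10	c.[1849T>T]+[1849T>A]	p.Y617N, p.Y617Y	13	-	0	0	10	0
NC_006088	1	185190031	T	C	N-syn	0.8	CCDC67	c.983A>G	p.Q328R	10	0	8	0	-	0
NC_006088	1	193338454	A	T	N-syn	1	ART7B	c.590T>A	p.L197Q	13	-	0	0	13	0
NC_006089	2	19385973	C	T	N-syn	1	LOC420515	c.3400G>A	p.V1134I	10	0	-	0	10	0
NC_006089	2	41279450	G	T	N-syn	1	TOPAZ1	c.2924C>A	p.T975N	10	0	0	-	10	0
NC_006089	2	42201510	T	T|C	N-syn	0.75	PIK3R4	c.[1937A>G]+[1937A>A]	p.D646D, p.D646G	12	0	9	0	-	0
NC_006089	2	63518627	T	C	N-syn	0.89	LOC101751154	c.137T>C	p.I46T	10	0	9	0	-	0
NC_006089	2	96924595	G	A	N-syn	1	PTPN2	c.934G>A	p.A312T	10	10	0	-	0	0
NC_006089	2	106000000	G	C	N-syn	0.9	COPN5L1	c.17C>G	p.A6G	11	1	10	-	0	0
NC_006089	2	121000000	T	C	N-syn	0.91	LOC101751416	c.194T>C	p.L65P	82	0	75	0	-	0
NC_006090	3	24479109	T	C	N-syn	1	THADA	c.859A>G	p.S287G	10	0	10	0	-	0
NC_006090	3	24515241	T	C	N-syn	1	PLEKHH2	c.1522T>C	p.F508L	10	0	10	0	-	0
NC_006090	3	37785831	A	G	N-syn	1	TARBP1	c.1321A>G	p.I441V	10	-	0	10	0	0
NC_006090	3	37785856	C	T	N-syn	1	TARBP1	c.1346C>T	p.T449I	10	0	-	0	10	0
NC_006090	3	38965704	G	T	N-syn	1	DISC1	c.1027C>A	p.L343I	10	0	0	-	10	0
NC_006090	3	105934067	C	G	N-syn	0.85	GVINP1	c.6146G>C	p.R2049T	14	0	-	12	0	0
NC_006091	4	120829955	C	T	N-syn	0.8	LOC771752	c.62G>A	p.R21Q	10	0	-	0	8	0
NC_006091	4	31100937	A	C	N-syn	0.9	TTC29	c.903T>G	p.D301E	11	-	10	0	0	0
NC_006091	4	56709491	G	G|A	N-syn	0.76	C4H4ORF21	c.[631G>G]+[631G>A]	p.D211N, p.D211D	13	10	0	-	0	0
NC_006091	4	60221486	C	T	N-syn	1	BANK1	c.934C>T	p.P312S	12	0	-	0	12	0
NC_006092	5	24297188	T	C	N-syn	1	MGA	c.7214T>C	p.M2405T	13	0	13	0	-	0
NC_006092	5	45169641	T	C	N-syn	1	LOC100858625	c.2191A>G	p.I731V	10	0	10	0	-	0
NC_006092	5	57915337	A	G	N-syn	0.86	TMX1	c.230A>G	p.D77G	15	-	0	13	0	0
NC_006093	6	130323	G	T	N-syn	1	FAM13C	c.1446G>T	p.E482D	10	0	0	-	10	0
NC_006093	6	23801282	T	C	N-syn	0.81	ITPRIP	c.1528A>G	p.I510V	11	0	9	0	-	0
NC_006094	7	4260582	C	T	N-syn	0.8	ABCA12	c.2110G>A	p.A704T	10	0	-	1	8	0
NC_006094	7	4717753	G	A	N-syn	0.8	RAB17	c.601G>A	p.V201I	10	8	0	-	0	0
NC_006094	7	4717765	G	A	N-syn	0.9	RAB17	c.613G>A	p.V205I	11	10	0	-	0	0
NC_006094	7	14344085	A	G	N-syn	1	ZNF385B	c.131A>G	p.H44R	13	-	0	13	0	0
NC_006094	7	15047308	A	G	N-syn	1	LOC770919	c.1253A>G	p.Y418C	10	-	0	10	0	0
NC_006094	7	15047322	A	G	N-syn	1	LOC770919	c.1267A>G	p.K423E	10	-	0	10	0	0
NC_006096	9	713606	G	A	N-syn	1	SAG	c.151G>A	p.V51M	13	13	0	-	0	0
NC_006096	9	20652272	T	C	N-syn	1	SI	c.2905T>C	p.S969P	11	0	11	0	-	0
NC_006096	9	21722478	G	A	N-syn	0.83	LOC425015	c.1352G>A	p.G451D	12	10	0	-	0	0
NC_006096	9	21722484	C	T	N-syn	0.8	LOC425015	c.1358C>T	p.P453L	10	0	-	0	8	0
NC_006096	9	22653344	T	G	N-syn	0.89	DHX36	c.333T>G	p.Y111.	10	0	0	9	-	1
NC_006097	10	11164703	C	T	N-syn	1	FAM154B	c.287G>A	p.R96K	11	0	-	0	11	0
NC_006098	11	9564860	G	A	N-syn	1	LRP3	c.2206G>A	p.G736R	10	10	0	-	0	0
NC_006099	12	5208897	A	G	N-syn	1	LOC100857401	c.3511A>G	p.K1171E	10	-	0	10	0	0
NC_006100	13	14403319	C	G	N-syn	0.9	LOC101749661	c.260G>C	p.G87A	11	0	-	10	0	0
NC_006101	14	12000000	T	C	N-syn	1	KIAA0556	c.2794A>G	p.N932D	10	0	10	0	-	0
NC_006101	14	13770765	A	G	N-syn	0.89	IFT140	c.2372A>G	p.K791R	10	-	0	9	0	0
NC_006102	15	10822742	T	C	N-syn	0.89	CCDC157	c.1492A>G	p.S498G	10	1	9	0	-	0
NC_006104	17	6833124	C	T	N-syn	0.83	GBGT1	c.368G>A	p.R123H	12	0	-	0	10	0
NC_006104	17	7711131	A	G	N-syn	1	PPP1R26	c.637A>G	p.I213V	11	-	0	11	0	0
NC_006106	19	5656736	C	T	N-syn	0.8	SLC46A1	c.1174G>A	p.G392S	10	0	-	0	8	0
NC_006107	20	43121	C	T	N-syn	1	IGSF1	c.412C>T	p.R138C	10	0	-	0	10	0
NC_006107	20	478926	C	T	N-syn	0.8	GGT7	c.1472C>T	p.S491F	10	0	-	0	8	0
NC_006107	20	4706188	G	T	N-syn	0.89	LOC101750167	c.619G>T	p.A207S	10	0	0	-	9	0
NC_006108	21	1906952	T	C	N-syn	1	TMEM52	c.2T>C	p.M1T	10	0	10	0	-	0
NC_006108	21	1906991	G	T	N-syn	1	TMEM52	c.41G>T	p.C14F	11	0	0	-	11	0
NC_006108	21	2451062	T	G	N-syn	0.89	SCNN1D	c.1912A>C	p.I638L	10	0	0	9	-	0
NC_006108	21	3241081	C	T	N-syn	1	SLC2A5	c.1246G>A	p.A416T	11	0	-	0	11	0
NC_006108	21	4662973	C	A	N-syn	0.89	EMC1	c.1070G>T	p.S357I	10	9	-	0	0	0
NC_006111	24	130579	C	T|C	N-syn	0.81	FEZ1	c.[1196C>T]+[1196C>C]	p.P399P, p.P399L	16	0	-	0	13	0
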