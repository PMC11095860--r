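chr1	11166587	11322614	MTOR
chr1	65298911	65432187	JAK1
chr2	39208689	39347604	SOS1
chr3	178866310	178952497	PIK3CA
chr4	55095263	55164414	PDGFRA
chr4	153242409	153456185	FBXW7
chr5	56111400	56191979	MAP3K1
chr5	112043194	112181936	APC
chr7	55086713	55324313	EGFR
chr7	140419126	140624564	BRAF
chr8	128747679	128753674	MYC
chr9	4985032	5128183	JAK2
chr9	5450502	5470567	CD274
chr9	21967751	21995043	CDKN2A
chr10	89622869	89731687	PTEN
chr12	25357722	25403870	KRAS
chr12	69201955	69239214	MDM2
chr14	105235685	105262088	AKT1
chr15	45003674	45011075	B2M
chr17	7565096	7590856	TP53
chr17	11924134	12047147	MAP2K4
chr17	29421944	29704695	NF1
chr17	37844166	37884915	ERBB2
chr19	1205797	1228431	STK11
chr19	10596795	10614417	KEAP1
chr19	11071597	11172958	SMARCA4
chr22	29999544	30094589	NF2
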