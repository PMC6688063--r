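group	individual	chrom	pos	ref	alt	location	caller	blood_ref	blood_alt	brain_ref	brain_alt	comments
LOAD	pair_01_02	chr1	207351003	C	A	Intergenic	mutect2	423	0	546	8	t_lod_fstar
LOAD	pair_01_02	chr1	207351003	C	A	Intergenic	strelka2	425	0	586	8	LowEVS
LOAD	pair_01_02	chr1	207351003	C	A	Intergenic	varscan2	424	0	584	7	PASS
LOAD	pair_19_20	chr1	207461994	C	T	Upstream CD55	mutect1	794	0	582	6	possible_contamination
LOAD	pair_19_20	chr1	207461994	C	T	Upstream CD55	mutect2	1472	0	997	10	PASS
LOAD	pair_19_20	chr1	207461994	C	T	Upstream CD55	strelka2	1476	0	1002	10	LowEVS
LOAD	pair_19_20	chr1	207461994	C	T	Upstream CD55	varscan2	1477	1	1001	10	PASS
EOAD	pair_27_28	chr1	207550332	T	C	Intergenic	mutect2	697	0	398	6	PASS
EOAD	pair_27_28	chr1	207550332	T	C	Intergenic	strelka2	701	0	400	6	LowEVS
EOAD	pair_27_28	chr1	207550332	T	C	Intergenic	varscan2	700	0	400	5	PASS
EOAD	pair_27_28	chr1	227069718	G	T	Missense PSEN2	mutect2	491	0	290	5	t_lod_fstar
EOAD	pair_27_28	chr1	227069718	G	T	Missense PSEN2	strelka2	490	0	289	5	LowEVS
EOAD	pair_27_28	chr1	227069718	G	T	Missense PSEN2	varscan2	490	0	287	5	PASS
EOAD	pair_25_26	chr2	128054946	G	T	Upstream ERCC3	mutect2	403	0	391	5	t_lod_fstar
EOAD	pair_25_26	chr2	128054946	G	T	Upstream ERCC3	strelka2	409	0	397	5	LowEVS
EOAD	pair_25_26	chr2	128054946	G	T	Upstream ERCC3	varscan2	409	0	396	5	PASS
EOAD	pair_11_12	chr8	27316070	C	A	3'UTR PTK2B	mutect2	332	0	414	6	t_lod_fstar
EOAD	pair_11_12	chr8	27316070	C	A	3'UTR PTK2B	strelka2	334	0	417	6	LowEVS
EOAD	pair_11_12	chr8	27316070	C	A	3'UTR PTK2B	varscan2	330	0	413	6	PASS
EOAD	pair_25_26	chr11	121250381	G	T	Intergenic	mutect2	394	0	467	7	t_lod_fstar
EOAD	pair_25_26	chr11	121250381	G	T	Intergenic	strelka2	394	0	473	7	LowEVS
EOAD	pair_25_26	chr11	121250381	G	T	Intergenic	varscan2	393	0	472	7	PASS
EOAD	pair_11_12	chr11	121363100	C	A	Intron SORL1	mutect2	609	1	209	6	t_lod_fstar
EOAD	pair_11_12	chr11	121363100	C	A	Intron SORL1	strelka2	614	1	222	6	PASS
EOAD	pair_11_12	chr11	121363100	C	A	Intron SORL1	varscan2	612	0	221	6	PASS
EOAD	pair_27_28	chr11	121401561	A	G	Intron SORL1	mutect2	880	0	391	6	t_lod_fstar
EOAD	pair_27_28	chr11	121401561	A	G	Intron SORL1	strelka2	882	0	392	6	LowEVS
EOAD	pair_27_28	chr11	121401561	A	G	Intron SORL1	varscan2	876	0	389	6	PASS
EOAD	pair_11_12	chr21	27421506	G	T	Intron APP	mutect2	696	0	371	5	t_lod_fstar
EOAD	pair_11_12	chr21	27421506	G	T	Intron APP	strelka2	704	0	428	5	LowEVS
EOAD	pair_11_12	chr21	27421506	G	T	Intron APP	varscan2	697	0	427	5	PASS
EOAD	pair_11_12	chr21	27489758	G	A	Intron APP	mutect2	987	0	579	6	t_lod_fstar
EOAD	pair_11_12	chr21	27489758	G	A	Intron APP	strelka2	987	0	594	6	LowEVS
EOAD	pair_11_12	chr21	27489758	G	A	Intron APP	varscan2	979	0	585	6	PASS
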