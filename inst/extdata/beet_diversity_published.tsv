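accession	crop_type	entry	total_variants	snp_variants	indel_variants	lsv_total	lsv_snp	lsv_indel	gene_diversity
EL10	sugar	1	221493	204260	17233	1149	689	460	0.027
C869	sugar	2	3479100	3147716	331384	9514	8290	1224	0.194
EL50	sugar	3	4226613	3805108	421505	30712	27667	3045	0.159
EL51	sugar	4	4222688	3808158	414530	17464	15547	1917	0.195
GP10	sugar	5	4070438	3689994	380444	9051	7999	1052	0.230
GP9	sugar	6	4216268	3803842	412426	6094	5366	728	0.253
L19	sugar	7	3492804	3185964	306840	19938	17854	2084	0.187
SP7322	sugar	8	4295147	3881458	413689	15528	13942	1586	0.213
SR102	sugar	9	4052933	3675246	377687	8765	7846	919	0.232
SR98	sugar	10	4097388	3702432	394956	16241	14612	1629	0.202
BBTB	table	11	4548634	4064552	484082	88129	79236	8893	0.087
Crosby	table	12	4553826	4112797	441029	21882	19436	2446	0.198
DDRT	table	13	4526694	4081640	445054	24180	21592	2588	0.185
RQ	table	14	4465888	4011300	454588	31786	28714	3072	0.154
TG	table	15	4066177	3655695	410482	37213	33887	3326	0.103
W357B	table	16	4096676	3674030	422646	81786	74941	6845	0.043
WT	table	17	4440187	3995032	445155	30371	27613	2758	0.159
MAM	fodder	18	3366421	3087403	279018	11969	10716	1253	0.221
WGF	fodder	19	4286092	3887565	398527	25210	22850	2360	0.202
FGSC	chard	20	5355215	4845307	509908	31764	28455	3309	0.241
LUC	chard	21	5228873	4745987	482886	35097	31341	3756	0.240
RHU	chard	22	4500515	4079774	420741	29089	26138	2951	0.195
Vulcan	chard	23	4852749	4378335	474414	37056	33650	3406	0.190
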