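crop_type	lsv_total	lsv_snp	lsv_indel	mean_2pq	sd_2pq
sugar	3659	3317	342	0.207	0.002
table	1937	1379	558	0.147	0.044
fodder	848	643	205	0.221	0.013
chard	4217	3359	858	0.216	0.027
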