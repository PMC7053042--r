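accession	chr1	chr2	chr3	chr4	chr5	chr6	chr7	chr8	chr9
EL10	91	170	103	114	96	229	147	95	104
BBTB	17632	10425	8148	9559	12067	9383	4597	6131	10187
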