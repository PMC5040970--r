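basis	class_name	experiments	cel_files	genes_filtered
process	Chemical	75	808	18026
process	Development	190	2252	17827
process	Hormone	116	1806	17646
process	Light	64	1210	17895
process	Metabolism	214	1535	17989
process	Pathogen	69	1156	17486
process	Stress	153	2476	19041
tissue	Flower	69	764	17209
tissue	Leaf	279	4268	17215
tissue	Root	121	1939	17775
tissue	Seedling	379	5234	17960
tissue	Whole Plant	144	2359	18805
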