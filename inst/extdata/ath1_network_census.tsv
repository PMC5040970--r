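network	method	dataset	input_arrays	genes_in_input	genes_in_network	edges
complete_A	pcc	complete_q0.65	11760	13384	2670	NA
complete_A	mi	complete_q0.65	11760	13384	13181	NA
complete_B	pcc	complete_qhist	11760	18806	3940	NA
complete_B	mi	complete_qhist	11760	18806	18606	NA
tissue_union	pcc	classified	NA	NA	7560	NA
process_union	pcc	classified	NA	NA	6858	NA
full_union	pcc	classified	NA	NA	8429	131648
tissue_union	mi	classified	NA	NA	19247	NA
process_union	mi	classified	NA	NA	20045	NA
full_union	mi	classified	NA	NA	20126	638051
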