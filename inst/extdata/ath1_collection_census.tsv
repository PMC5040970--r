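database	experiments	cel_files	qc_filtered
ArrayExpress	543	7923	848
GEO	83	1270	102
NASC	211	2859	387
AtGenExpress	44	1334	289
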