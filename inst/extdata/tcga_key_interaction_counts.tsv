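cancer_type	n_interactions	n_mirnas	n_targets
BLCA	203	21	109
BRCA	93	23	85
CESC	31	17	23
COAD	4	3	3
ESCA	12	9	10
GBM	528	51	467
HNSC	115	9	114
KIRC	580	65	424
KIRP	181	34	163
LIHC	71	17	65
LUAD	51	19	41
LUSC	6	6	6
OV	84	37	59
PAAD	3	2	3
STAD	7	4	7
THCA	10	8	9
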