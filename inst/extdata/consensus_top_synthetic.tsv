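gene_id	cell_type	measure	agg_stat	n_present	consensus_rank
AQP4	AST	specificity	6.10	5	1
SLC1A2	AST	specificity	5.80	5	2
GJA1	AST	specificity	5.20	4	3
GFAP	AST	specificity	4.90	5	4
ALDH1L1	AST	specificity	4.40	3	5
CCL3	MIC	specificity	6.40	5	1
CCL4	MIC	specificity	6.10	5	2
CX3CR1	MIC	specificity	5.70	4	3
P2RY12	MIC	specificity	5.30	3	4
TMEM119	MIC	specificity	4.80	3	5
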