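# source: published TC-YIK neurosecretory peptide expression (focal TPM, rank among 988 panel samples, panel maximum)
# columns: gene, tpm_focal, rank, max_tpm
gene	tpm_focal	rank	max_tpm
CHGA	6062.51	1	6062.51
TTR	1202.73	21	60441.3
GAST	1096.66	1	1096.66
INS	50.13	4	5119.98
GHRL	15.37	5	54.13
SST	7.81	93	3612.79
IAPP	0	NA	26.58
GCG	0	NA	3534.95
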