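# source: published TC-YIK TF enrichment table (focal TPM, log10 pseudocounted enrichment over the 988-sample panel median, literature flags)
# columns: tf_symbol, tpm, enrichment_score, pancreatic_biology, mouse_developing_pancreas, experiments
tf_symbol	tpm	enrichment_score	pancreatic_biology	mouse_developing_pancreas	experiments
NEUROD1	593	2.77	yes	yes	Si,CA,CS
INSM1	519	2.72	yes	yes	-
PAX6	296	2.47	yes	yes	Si,CA,CS
NKX6-3	239	2.38	yes	no	-
ARX	237	2.38	yes	yes	Si
MLXIPL	218	2.34	yes	yes	Si,CA
RFX6	146	2.17	yes	yes	Si,CA,CS
ONECUT2	151	2.14	yes	yes	Si,CA
PAX4	133	2.13	yes	yes	Si,CA
PDX1	127	2.11	yes	yes	Si
DACH1	269	2.05	yes	yes	Si,CA
ISL1	102	2.01	yes	yes	Si,CA,CS
FEV	94	1.98	yes	no	Si
HOPX	168	1.95	yes	yes	Si,CA
FOXA2	88	1.95	yes	yes	Si
ST18	78	1.90	yes	yes	-
HNF4G	75	1.88	yes	yes	-
PROX1	106	1.84	yes	yes	Si,CA
HNF4A	69	1.84	yes	yes	Si
ELF3	51	1.71	yes	yes	Si
SHOX2	62	1.70	yes	no	Si,CA
NPAS3	55	1.63	no	yes	-
CDX2	41	1.63	yes	yes	-
HOXA10	40	1.61	yes	no	Si
MNX1	38	1.59	yes	yes	Si,CA
ASCL2	34	1.54	no	yes	-
TFAP2A	97	1.53	yes	no	-
IRF8	31	1.51	no	yes	Si
CASZ1	70	1.51	yes	yes	-
SIX3	30	1.49	no	no	Si
MYRF	62	1.49	no	yes	-
MYT1	26	1.43	yes	yes	Si
HOXB13	26	1.43	yes	no	Si
ASCL1	25	1.42	yes	yes	Si,CA
NR0B2	24	1.41	yes	yes	Si
LMX1A	24	1.40	yes	no	Si,CA,CS
HSF4	27	1.33	no	yes	-
HES6	71	1.32	yes	yes	-
HLF	23	1.31	no	yes	Si
IRF6	23	1.30	no	yes	-
DLX6	19	1.29	no	no	Si
GATA4	18	1.28	yes	yes	Si,CA
ATF5	290	0.73	no	yes	Si,CA
HMGB2	243	0.37	no	yes	Si,CA
GTF3A	213	0.36	no	yes	Si,CA
HMGA1	672	0.34	yes	yes	Si,CA
TBP	29	0.15	no	yes	Si,CA
TAF9	80	0.09	no	yes	Si,CA
TCF25	90	-0.10	no	yes	Si,CA
TAF10	75	-0.33	no	yes	Si,CA
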