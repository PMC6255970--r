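go_id	ontology	description	k	K	p_value	fdr
GO:0006950	P	Response to stress	75	3705	3.90E-44	1.00E-41
GO:0009628	P	Response to abiotic stimulus	60	2423	3.70E-37	4.80E-35
GO:0009414	P	Response to water deprivation	31	374	1.70E-32	1.40E-30
GO:0009415	P	Response to water	31	393	6.90E-32	4.40E-30
GO:0050896	P	Response to stimulus	77	6230	1.40E-30	7.40E-29
GO:0009266	P	Response to temperature stimulus	34	902	5.70E-25	2.40E-23
GO:0042221	P	Response to chemical stimulus	53	3244	2.90E-23	1.10E-21
GO:0009409	P	Response to cold	27	625	3.60E-21	1.20E-19
GO:0009737	P	Response to abscisic acid stimulus	27	664	1.60E-20	4.60E-19
GO:0006970	P	Response to osmotic stress	25	631	9.70E-19	2.50E-17
GO:0010033	P	Response to organic substance	37	2117	2.80E-16	6.40E-15
GO:0009651	P	Response to salt stress	21	536	1.00E-15	2.20E-14
GO:0009725	P	Response to hormone stimulus	32	1601	1.50E-15	2.90E-14
GO:0009719	P	Response to endogenous stimulus	32	1755	1.80E-14	3.30E-13
GO:0070887	P	Cellular response to chemical stimulus	24	941	7.00E-14	1.20E-12
GO:0006979	P	Response to oxidative stress	20	605	1.20E-13	1.90E-12
GO:0009269	P	Response to desiccation	10	71	4.30E-13	6.50E-12
GO:0008152	P	Metabolic process	87	14876	1.30E-12	1.90E-11
GO:0051716	P	Cellular response to stimulus	28	1595	3.00E-12	3.80E-11
GO:0044248	P	Cellular catabolic process	26	1352	3.00E-12	3.80E-11
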