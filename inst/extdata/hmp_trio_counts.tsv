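site	treatment	with_MAO:1A	with_MAO:1B	with_MAO:2A	with_MAO:2B	with_MAO:3	with_MAO:4	without_MAO:---	without_MAO:+--	without_MAO:++-	without_MAO:+++	SLM:-	SLM:+	DLM:--	DLM:-+	DLM:++	TLM:---	TLM:--+	TLM:-++	TLM:+++
gut	HIV-Negative	36	14	0	0	0	86	0	365	0	2127549	1029	311	207	123	286	8	37	76	239
gut	HIV-ART	11	22	0	0	0	4	0	125	0	1683975	434	21	171	17	1	24	13	3	1
gut	HIV-NonART	3	0	0	0	0	110	0	43	0	1876511	1	1381	0	2	260	0	0	2	240
gut	IBD-Healthy	0	0	0	0	0	2	0	0	0	278775	0	1	0	0	0	0	0	0	0
gut	IBD-CD	0	0	0	0	0	5	0	0	0	86738	0	25	0	0	4	0	0	0	1
gut	IBD-UC	1	0	0	0	0	34	0	11	0	280215	8	633	0	1	123	0	0	1	71
lung	Lung-EndOfTreatment	0	0	0	0	0	0	0	0	0	562	0	0	0	0	0	0	0	0	0
lung	Lung-Exacerbation	1	0	0	0	0	0	0	0	0	1055	0	0	0	0	0	0	0	0	0
oral	Oral-Healthy	0	21	0	0	0	0	0	27	0	42155	485	0	192	0	0	27	0	0	0
oral	Oral-PB	0	0	0	0	0	0	0	3	0	9783	0	2	0	0	0	0	0	0	0
oral	Oral-PnB	0	0	0	0	0	0	0	0	0	11607	0	0	0	0	0	0	0	0	0
skin	Skin-Healthy	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
skin	Skin-AD	0	30	0	0	0	0	0	0	0	65	2	0	10	0	0	53	0	0	0
vaginal	Vaginal-Healthy	0	0	0	0	0	0	0	1	0	5327	1	0	0	0	0	0	0	0	0
vaginal	Vaginal-BV	6	17	0	0	0	2	0	39	0	428	60	24	31	14	3	1	4	6	10
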