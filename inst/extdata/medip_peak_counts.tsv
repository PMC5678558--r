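chrom	ap13_total	ap13_annotated	vs16_total	vs16_annotated	length_mb	ap13_total_per_mb	ap13_annotated_per_mb	vs16_total_per_mb	vs16_annotated_per_mb
Chr01a	9383	1298	6610	953	97.81	95.93	13.27	67.58	9.74
Chr01b	8176	1230	5673	907	80.38	101.71	15.30	70.57	11.28
Chr02a	10727	1502	7608	1165	103.95	103.20	14.45	73.19	11.21
Chr02b	9030	1296	6631	1035	93.55	96.52	13.85	70.88	11.06
Chr03a	7695	1339	5610	1004	73.00	105.41	18.34	76.85	13.75
Chr03b	5355	729	3697	533	57.82	92.62	12.61	63.94	9.22
Chr04a	6214	949	4312	686	63.56	97.76	14.93	67.84	10.79
Chr04b	5599	820	3813	584	56.30	99.44	14.56	67.72	10.37
Chr05a	11457	1836	8246	1406	116.48	98.36	15.76	70.79	12.07
Chr05b	10597	1575	7576	1200	100.40	105.55	15.69	75.46	11.95
Chr06a	6429	957	4663	744	72.90	88.19	13.13	63.97	10.21
Chr06b	7013	801	5118	626	80.13	87.53	10.00	63.87	7.81
Chr07a	6179	953	4392	731	75.76	81.56	12.58	57.97	9.65
Chr07b	6646	978	4721	738	70.77	93.91	13.82	66.71	10.40
Chr08a	5524	720	3774	520	73.87	74.78	9.75	51.09	7.04
Chr08b	5968	733	3762	517	77.82	76.69	9.42	48.34	6.64
Chr09a	12929	1845	9148	1397	122.78	105.30	15.03	74.51	11.38
Chr09b	9541	1460	7322	1189	87.97	108.46	16.60	83.23	13.52
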