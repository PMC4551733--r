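chrom	chr_size_umd_mb	chr_size_btau_mb	n_seg_umd	n_seg_btau	ave_seg_umd_mb	ave_seg_btau_mb	mass_umd_mb	mass_btau_mb	coverage_umd_pct	coverage_btau_pct
chr1	158.34	161.43	5	8	27.92	15.79	139.62	126.30	88.18	78.24
chr2	137.06	141.97	2	6	60.62	18.95	121.23	113.72	88.45	80.10
chr3	121.43	126.84	3	10	34.80	9.83	104.41	98.33	85.98	77.52
chr4	120.83	123.81	5	4	21.32	24.88	106.58	99.53	88.21	80.39
chr5	121.19	125.25	7	6	15.23	16.34	106.64	98.04	87.99	78.28
chr6	119.46	122.52	3	5	34.84	18.58	104.52	92.88	87.49	75.81
chr7	112.64	113.03	5	9	18.89	9.62	94.45	86.54	83.85	76.56
chr8	113.38	116.85	3	4	32.64	22.60	97.92	90.39	86.36	77.36
chr9	105.71	108.50	2	4	46.94	21.40	93.88	85.58	88.81	78.88
chr10	104.31	105.98	7	8	14.22	10.58	99.52	84.66	95.41	79.88
chr11	107.31	109.99	2	11	47.66	8.10	95.31	89.15	88.82	81.05
chr12	91.16	85.12	2	6	38.06	11.31	76.11	67.85	83.49	79.71
chr13	84.24	84.21	2	4	37.09	17.34	74.17	69.34	88.05	82.34
chr14	84.65	81.22	3	5	24.44	13.31	73.32	66.53	86.62	81.91
chr15	85.30	84.47	5	8	14.49	7.90	72.45	63.17	84.94	74.78
chr16	81.72	77.71	9	8	7.57	7.45	68.15	59.57	83.39	76.66
chr17	75.16	76.28	2	3	32.56	19.77	65.12	59.31	86.64	77.75
chr18	66.00	65.81	7	7	6.88	6.09	48.15	42.60	72.95	64.73
chr19	64.06	64.85	6	8	8.96	6.34	53.77	50.68	83.94	78.15
chr20	72.04	75.69	1	2	63.53	29.96	63.53	59.92	88.19	79.17
chr21	71.60	69.08	4	5	15.54	10.86	62.17	54.29	86.83	78.59
chr22	61.44	61.60	3	4	17.80	12.20	53.40	48.78	86.91	79.19
chr23	52.53	52.33	2	3	22.83	13.98	45.65	41.94	86.90	80.15
chr24	62.71	64.51	1	5	56.86	10.54	56.86	52.72	90.67	81.72
chr25	42.90	44.08	2	4	18.16	8.47	36.31	33.89	84.64	76.88
chr26	51.68	51.83	1	2	43.31	18.89	43.31	37.78	83.80	72.89
chr27	45.41	48.46	1	2	38.83	18.52	38.83	37.03	85.51	76.41
chr28	46.31	45.96	4	4	10.27	9.30	41.09	37.18	88.73	80.90
chr29	51.51	51.81	3	2	14.34	19.57	43.02	39.13	83.52	75.53
chrX	148.82	88.65	33	31	3.56	2.19	117.59	67.91	79.01	76.60
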