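contig	chrom	size_mb	ave_frag_kb	n_fragments	pooled_sd	n_rmaps	coverage_x	chr_end
BtOMcontig_0	chr1_OM	140.22	10.06	13939	1.44	30977	86.44	NA
BtOMcontig_1	chr2_OM	130.23	9.14	14255	1.38	25002	74.86	NA
BtOMcontig_2	chr6_OM	118.45	9.95	11903	1.43	31660	104.35	NA
BtOMcontig_3	chr4_OM	116.61	9.48	12301	1.43	25518	85.52	NA
BtOMcontig_4	chr11_OM	106.25	8.62	12319	1.34	21601	79.32	NA
BtOMcontig_5	chr3_OM	93.84	8.99	10443	1.38	19179	79.65	NA
BtOMcontig_6	chr7_OM	87.27	9.68	9015	1.43	20409	91.23	Rend
BtOMcontig_7	chr9_OM	84.26	10.48	8036	1.47	21152	98.28	NA
BtOMcontig_8	chr14_OM	79.81	9.30	8580	1.37	19868	96.42	Rend
BtOMcontig_9	chr10_OM	78.66	9.16	8584	1.37	16881	83.57	NA
BtOMcontig_10	chr5_OM	72.42	9.55	7580	1.42	16341	87.99	NA
BtOMcontig_11	chr20_OM	70.31	9.25	7598	1.38	16064	88.57	Rend
BtOMcontig_12	chr17_OM	69.22	8.87	7802	1.38	15249	85.40	NA
BtOMcontig_13	chr12_OM	68.49	10.06	6806	1.44	17380	99.26	NA
BtOMcontig_14	chr8_OM	67.78	9.44	7180	1.38	16346	93.45	NA
BtOMcontig_15	chr24_OM	61.70	8.83	6985	1.34	13714	85.83	NA
BtOMcontig_16	chr23_OM	51.93	8.12	6397	1.27	11238	83.85	Rend
BtOMcontig_17	chr21_OM	48.96	8.42	5814	1.32	10942	86.52	NA
BtOMcontig_18	chrX_OM	48.92	9.31	5252	1.39	12327	97.76	NA
BtOMcontig_19	chr22_OM	48.65	8.60	5658	1.31	11716	92.87	NA
BtOMcontig_20	chr26_OM	48.38	8.52	5679	1.33	9439	75.22	NA
BtOMcontig_21	chr27_OM	45.27	8.75	5172	1.33	9906	84.89	Lend
BtOMcontig_22	chr28_OM	42.83	8.66	4948	1.32	8814	79.69	NA
BtOMcontig_23	chr13_OM	42.25	7.24	5838	1.19	7245	65.93	Rend
BtOMcontig_24	chr8_OM	41.52	8.52	4873	1.31	8742	81.62	Rend
BtOMcontig_25	chr15_OM	41.17	8.51	4838	1.16	12747	120.55	NA
BtOMcontig_26	chr13_OM	40.80	8.65	4716	1.31	10335	98.34	NA
BtOMcontig_27	chr16_OM	40.45	9.14	4426	1.38	9294	89.46	NA
BtOMcontig_28	chr29_OM	38.81	8.50	4564	1.20	8285	82.48	NA
BtOMcontig_29	chr18_OM	37.17	7.77	4784	1.25	6532	67.64	NA
BtOMcontig_30	chr25_OM	35.31	7.07	4994	1.16	5605	60.68	NA
BtOMcontig_31	chr15_OM	33.58	9.29	3615	1.38	7351	85.37	NA
BtOMcontig_32	chrX_OM	31.48	10.26	3068	1.47	8223	101.92	NA
BtOMcontig_33	chr5_OM	30.96	9.21	3361	1.39	6918	87.43	NA
BtOMcontig_34	chr16_OM	26.17	8.47	3089	1.29	5361	79.51	Rend
BtOMcontig_35	chr19_OM	24.87	7.02	3543	1.18	4275	65.31	NA
BtOMcontig_36	chr10_OM	22.97	8.23	2791	1.28	4012	67.92	NA
BtOMcontig_37	chr21_OM	20.02	8.91	2247	1.33	4576	88.83	NA
BtOMcontig_38	chrX_OM	18.25	9.23	1978	1.39	3883	82.28	NA
BtOMcontig_39	chrX_OM	17.09	9.89	1728	1.31	4286	98.13	Lend
BtOMcontig_40	chr9_OM	17.02	8.49	2004	1.29	3479	79.17	Rend
BtOMcontig_41	chr19_OM	16.07	8.79	1827	1.33	3955	95.33	NA
BtOMcontig_42	chr12_OM	14.86	8.79	1690	1.27	3990	104.20	Rend
BtOMcontig_43	chr7_OM	14.62	6.60	2214	1.16	2335	61.06	NA
BtOMcontig_44	chr3_OM	13.22	7.30	1812	1.14	2100	61.76	NA
BtOMcontig_45	chr29_OM	12.61	6.83	1845	1.06	1845	55.85	Rend
BtOMcontig_46	chr1_OM	12.49	8.23	1518	1.28	2545	79.47	Rend
BtOMcontig_47	chrX_OM	12.13	8.23	1474	1.27	2933	93.12	Rend
BtOMcontig_48	chr18_OM	11.51	7.94	1450	1.23	2317	77.67	NA
BtOMcontig_49	chr5_OM	10.61	7.02	1511	1.15	1527	55.98	Rend
BtOMcontig_50	chr22_OM	10.42	7.10	1467	1.20	2247	82.47	Rend
BtOMcontig_51	chrX_OM	9.25	9.92	933	1.35	1879	79.61	NA
BtOMcontig_52	chr19_OM	8.80	6.81	1292	1.14	1385	60.46	NA
BtOMcontig_53	chr3_OM	8.48	8.67	978	1.25	1625	74.62	NA
BtOMcontig_54	chr25_OM	7.44	7.33	1015	1.23	1260	65.72	NA
BtOMcontig_55	chr15_OM	7.05	8.17	863	1.21	1405	76.14	Rend
BtOMcontig_56	chr16_OM	6.81	8.19	832	1.26	1304	74.28	NA
BtOMcontig_57	chr19_OM	6.62	7.18	922	1.18	1280	75.50	Rend
BtOMcontig_58	chrX_OM	5.20	8.20	634	1.36	1403	101.81	NA
BtOMcontig_59	chr7_OM	5.14	7.13	721	1.06	767	57.86	NA
BtOMcontig_60	chr16_OM	4.11	7.18	573	1.18	677	62.75	NA
BtOMcontig_61	chrX_OM	4.07	9.14	445	1.33	1085	102.82	NA
BtOMcontig_62	chrX_OM	3.61	8.68	416	1.39	667	71.57	NA
BtOMcontig_63	chrX_OM	3.51	8.70	404	1.33	751	81.90	NA
BtOMcontig_64	chr19_OM	3.19	6.20	514	1.08	367	43.19	NA
BtOMcontig_65	chr5_OM	3.10	7.01	442	1.18	456	55.52	NA
BtOMcontig_66	chr28_OM	3.01	9.48	318	1.20	522	68.20	NA
BtOMcontig_67	chr17_OM	2.46	6.79	363	1.19	369	58.72	Rend
BtOMcontig_68	chr19_OM	2.39	6.75	354	1.11	359	57.08	NA
BtOMcontig_69	chr18_OM	2.37	6.96	341	1.13	367	59.18	Rend
BtOMcontig_70	chrX_OM	2.34	12.14	193	1.44	439	73.01	NA
BtOMcontig_71	chr18_OM	1.71	6.14	278	1.03	192	43.46	NA
BtOMcontig_72	chr14_OM	1.48	8.95	165	1.22	150	38.00	NA
BtOMcontig_73	chr16_OM	1.04	7.06	148	1.19	90	32.43	NA
BtOMcontig_74	chr18_OM	0.95	6.39	148	1.11	110	43.36	NA
BtOMcontig_75	chr14_OM	0.84	7.09	119	1.19	100	46.05	NA
BtOMcontig_76	chr18_OM	0.75	6.08	124	1.10	90	45.00	NA
BtOMcontig_77	chr18_OM	0.66	6.00	110	1.04	121	67.59	NA
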