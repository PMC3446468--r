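marker_id	locus	chromosome_type	phase	or_mh	in_battery	subgroup_bias	or_ratio_sn	raf_central	raf_southern	rxy	slope
rs1143679	ITGAM	autosomal	phase1	1.70	yes	southern	1.25	11.9	16.7	-0.59	-4.79
rs7574865	STAT4	autosomal	phase1	1.52	yes	southern	1.25	23.3	23.8	-0.51	-4.63
rs13277113	C8orf13-BLK	autosomal	phase1	1.34	yes	southern	1.25	31.0	23.2	0.20	0.95
rs2304256	TYK2	autosomal	phase1	1.32	yes	southern	1.25	73.1	71.0	0.06	0.23
rs17435	MECP2	x_linked	phase1	1.27	yes	southern	1.25	20.9	22.8	-0.57	-2.84
rs10798269	1q25.1	autosomal	phase1	1.25	yes	southern	1.25	66.2	69.0	-0.17	-1.16
rs17266594	BANK1	autosomal	phase1	1.23	yes	southern	1.25	71.2	70.9	0.32	1.99
rs4963128	KIAA1542	autosomal	phase1	1.19	yes	central	0.80	69.1	65.3	0.58	2.83
rs6445975	PXK	autosomal	phase1	1.15	yes	southern	1.25	29.0	22.6	0.66	2.67
rs3131379	MSH5	autosomal	phase2	2.25	yes	southern	2.00	14.9	4.6	0.92	4.15
rs2187668	HLA-DQA1	autosomal	phase2	2.17	yes	southern	1.55	15.7	8.7	0.88	4.93
rs10488631	IRF5	autosomal	phase2	2.00	yes	southern	1.25	11.6	9.3	0.46	3.64
rs2230926	TNFAIP3	autosomal	phase2	1.99	yes	southern	1.25	3.5	4.3	-0.21	-3.42
rs729302	IRF5	autosomal	phase2	1.35	yes	central	0.80	67.8	69.0	-0.00	-0.03
rs2476601	PTPN22	autosomal	phase2	1.34	yes	southern	1.25	11.8	6.1	0.74	4.21
rs5754217	UBE2L3	autosomal	phase2	1.26	yes	central	0.80	22.8	20.8	0.16	1.28
rs2205960	TNFSF4	autosomal	phase2	1.25	yes	equal	1.00	25.2	20.7	0.15	1.08
rs6920220	TNFAIP3	autosomal	phase2	1.21	yes	southern	1.25	19.3	17.8	0.49	2.74
rs844644	TNFSF4	autosomal	phase2	1.19	no	NA	NA	NA	NA	NA	NA
rs1801274	FCGR2A	autosomal	phase2	1.18	yes	southern	1.25	44.5	48.6	-0.40	-1.25
rs573775	ATG5	autosomal	phase2	1.17	yes	central	0.80	28.2	26.3	0.51	4.10
rs10156091	ICA1	autosomal	phase2	1.09	no	NA	NA	NA	NA	NA	NA
rs4240671	XKR6	autosomal	phase2	1.09	no	NA	NA	NA	NA	NA	NA
rs2667978	LYN	autosomal	phase2	1.06	no	NA	NA	NA	NA	NA	NA
rs6922466	PERP	autosomal	phase2	1.02	no	NA	NA	NA	NA	NA	NA
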