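collection_id	n_controls	n_cases	women_controls_pct	women_cases_pct	rs12913832	rs382259	rs6730157	ns_score_published	subgroup	aim_qc_excluded
NL	180	104	59.4	86.5	83.0	77.6	72.5	100.0	central	no
BE	106	147	93.5	90.5	NA	NA	NA	NA	central	yes
DE	95	90	NA	90	77.9	68.1	56.9	80.5	central	no
CZ	100	101	32	85.1	NA	NA	NA	NA	central	yes
SK	93	94	93.5	91.5	72.8	63.8	39.4	64.4	central	no
HU	95	95	48.4	90.4	63.4	59.6	39.0	54.9	central	no
ES, LCG	145	88	82.9	92	35.4	67.4	45.3	47.6	southern	no
ES, OVD	200	147	69	91.8	30.5	70.4	45.4	47.2	southern	no
ES, SCQ	95	109	48.4	96	35.1	68.2	41.3	46.0	southern	no
ES, BCN	97	90	52.6	91.1	32.6	63.2	41.6	40.5	southern	no
ES, MAD	281	92	68.8	91.3	33.1	61.9	42.3	40.0	southern	no
PT	97	100	91.3	95.3	28.7	60.7	39.1	34.6	southern	no
IT, MXP	106	129	42.5	86.8	47.6	49.1	19.8	26.2	southern	no
IT, ROM	102	84	55.9	89.7	38.2	51.9	15.3	20.3	southern	no
GR, AUMS	100	95	92	91.6	36.0	44.0	13.4	11.3	southern	no
IT, NAP	109	79	100	90.1	38.6	42.2	10.0	9.6	southern	no
GR, EH	100	98	67	86.7	36.7	38.0	13.5	6.8	southern	no
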