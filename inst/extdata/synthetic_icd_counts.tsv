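sample_id	variant_id	gene_id	ref_count_U	alt_count_U	ref_count_T	alt_count_T
s1	gene00001_v1	gene00001	27	33	31	29
s1	gene00001_v2	gene00001	71	49	32	28
s1	gene00002_v1	gene00002	54	66	27	33
s1	gene00002_v2	gene00002	44	76	46	74
s1	gene00003_v1	gene00003	62	58	64	56
s1	gene00003_v2	gene00003	32	28	76	44
s1	gene00003_v3	gene00003	78	42	78	42
s1	gene00004_v1	gene00004	24	36	61	59
s1	gene00004_v2	gene00004	73	47	74	46
s1	gene00005_v1	gene00005	53	67	48	72
s1	gene00005_v2	gene00005	27	33	31	29
s1	gene00006_v1	gene00006	63	57	33	27
s1	gene00006_v2	gene00006	31	29	59	61
s1	gene00006_v3	gene00006	22	38	26	34
s1	gene00007_v1	gene00007	14	46	22	38
s1	gene00007_v2	gene00007	34	86	23	37
s1	gene00007_v3	gene00007	39	21	52	68
s1	gene00008_v1	gene00008	30	90	17	43
s1	gene00008_v2	gene00008	78	42	34	26
s1	gene00008_v3	gene00008	25	35	53	67
s1	gene00009_v1	gene00009	43	77	44	76
s1	gene00009_v2	gene00009	68	52	32	28
s1	gene00010_v1	gene00010	32	28	69	51
s1	gene00010_v2	gene00010	26	34	50	70
s1	gene00010_v3	gene00010	26	34	30	30
s1	gene00011_v1	gene00011	56	64	60	60
s1	gene00011_v2	gene00011	20	40	41	79
s1	gene00011_v3	gene00011	50	70	24	36
s1	gene00012_v1	gene00012	20	40	40	80
s1	gene00012_v2	gene00012	34	26	63	57
s1	ASEG1_v1	ASEG1	44	76	50	10
s1	ASEG1_v2	ASEG1	36	24	112	8
s1	ASEG2_v1	ASEG2	65	55	11	109
s1	ASEG2_v2	ASEG2	68	52	12	48
s1	ASEG3_v1	ASEG3	29	31	53	7
s1	ASEG3_v2	ASEG3	61	59	105	15
s1	ASEG4_v1	ASEG4	34	26	10	110
s1	ASEG4_v2	ASEG4	22	38	4	56
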