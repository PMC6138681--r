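feature_id	panel	function_group	median_Sham	iqr_Sham	median_IR	iqr_IR	median_IRT3	iqr_IRT3	flag_star	flag_hash	flag_irt3_vs_sham
Bak1	MPA	apoptosis_membrane	0.92	0.39	4.6	1.5	1.75	0.49	TRUE	TRUE	TRUE
Bbc3	MPA	apoptosis_membrane	0.99	0.19	2.28	0.48	1.47	0.3	TRUE	TRUE	TRUE
Bid	MPA	apoptosis_membrane	0.94	0.52	15	5.1	7.1	2.55	TRUE	TRUE	TRUE
Bnip3	MPA	apoptosis_membrane	1.05	0.36	0.43	0.22	0.94	0.18	TRUE	TRUE	FALSE
Cdkn2a	MPA	apoptosis_membrane	0.95	0.72	20.9	4.6	14.4	4.2	TRUE	TRUE	TRUE
Gclc	MPA	apoptosis_membrane	0.97	0.82	4.2	1.35	2.09	0.65	TRUE	TRUE	TRUE
Pmaip1	MPA	apoptosis_membrane	0.92	0.54	2.29	0.59	1.37	0.39	TRUE	TRUE	FALSE
Sfn	MPA	apoptosis_membrane	1.06	0.91	2.8	1.39	1.02	0.21	TRUE	TRUE	FALSE
Tp53	MPA	apoptosis_membrane	0.92	0.29	2.85	0.13	2.0	0.54	TRUE	TRUE	TRUE
Cpt1b	MPA	metabolite_transport	1.03	0.61	0.39	0.18	1.04	0.29	TRUE	TRUE	FALSE
Cpt2	MPA	metabolite_transport	1.05	0.28	0.43	0.16	0.95	0.46	TRUE	TRUE	FALSE
Tspo	MPA	metabolite_transport	1.06	0.48	1.69	0.36	2.04	0.54	TRUE	FALSE	TRUE
Slc25a10	MPA	metabolite_transport	1.19	0.92	2.1	0.44	0.97	0.35	TRUE	TRUE	FALSE
Slc25a12	MPA	metabolite_transport	1.13	0.36	0.49	0.17	0.88	0.33	TRUE	TRUE	FALSE
Slc25a13	MPA	metabolite_transport	1.18	0.25	0.55	0.08	0.88	0.1	TRUE	TRUE	FALSE
Slc25a16	MPA	metabolite_transport	1.0	0.22	2.03	0.27	1.45	0.14	TRUE	TRUE	TRUE
Slc25a17	MPA	metabolite_transport	1.12	0.22	2.78	0.41	2.5	0.66	TRUE	FALSE	TRUE
Slc25a20	MPA	metabolite_transport	1.04	0.34	0.39	0.13	0.76	0.14	TRUE	TRUE	FALSE
Slc25a21	MPA	metabolite_transport	1.2	0.44	0.26	0.21	0.27	0.14	TRUE	FALSE	TRUE
Slc25a24	MPA	metabolite_transport	1.08	0.62	10.2	2.58	5.37	1.71	TRUE	TRUE	TRUE
Slc25a25	MPA	metabolite_transport	0.93	0.83	0.3	0.12	0.44	0.14	TRUE	FALSE	TRUE
Slc25a3	MPA	metabolite_transport	1.15	0.36	0.38	0.09	0.79	0.3	TRUE	TRUE	FALSE
Slc25a37	MPA	metabolite_transport	1.03	0.74	2.27	0.09	1.58	0.2	TRUE	TRUE	TRUE
Cln8	MPA	protein_import	1.08	0.73	3.06	1.23	1.96	0.34	TRUE	TRUE	TRUE
Hsp90aa1	MPA	protein_import	1.02	0.36	2.18	0.44	1.76	0.29	TRUE	FALSE	TRUE
Mtx2	MPA	protein_import	0.97	0.18	0.63	0.12	0.96	0.22	TRUE	TRUE	FALSE
Timm10	MPA	protein_import	1.04	0.38	0.47	0.09	0.53	0.07	TRUE	FALSE	TRUE
Timm17a	MPA	protein_import	1.18	0.25	0.4	0.11	0.65	0.11	TRUE	TRUE	TRUE
Timm8b	MPA	protein_import	1.07	0.21	0.42	0.18	0.64	0.13	TRUE	TRUE	TRUE
Ppargc1a	MPA	replication_function	1.05	0.34	0.26	0.14	0.73	0.24	TRUE	TRUE	FALSE
Mfn1	MPA	replication_function	1.07	0.42	0.55	0.09	0.92	0.14	TRUE	TRUE	FALSE
Mfn2	MPA	replication_function	1.05	0.61	0.49	0.17	0.9	0.42	TRUE	TRUE	FALSE
Msto1	MPA	replication_function	1.14	0.31	2.75	0.63	0.96	0.51	TRUE	TRUE	FALSE
Rnf135	MPA	replication_function	0.92	0.67	3.93	1.3	1.7	0.46	TRUE	TRUE	TRUE
Sod1	MPA	replication_function	1	0.23	0.6	0.08	0.94	0.17	TRUE	TRUE	FALSE
Sod2	MPA	replication_function	1.17	0.33	0.7	0.15	1.24	0.55	TRUE	TRUE	FALSE
Ucp4	MPA	replication_function	1.09	0.49	2.53	1.05	1.01	0.34	TRUE	TRUE	FALSE
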