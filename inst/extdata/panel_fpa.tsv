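feature_id	panel	function_group	median_Sham	iqr_Sham	median_IR	iqr_IR	median_IRT3	iqr_IRT3	flag_star	flag_hash	flag_irt3_vs_sham
Col1a2	FPA	ecm_remodeling	0.77	0.23	15.8	0.48	8.60	4.0	TRUE	TRUE	TRUE
Col3a1	FPA	ecm_remodeling	0.85	0.22	15.7	3.5	8.26	4.60	TRUE	TRUE	TRUE
Mmp2	FPA	ecm_remodeling	0.76	0.50	6.42	1.23	1.84	0.96	TRUE	TRUE	TRUE
Mmp8	FPA	ecm_remodeling	0.38	0.66	5.82	2.24	2.62	1.90	TRUE	TRUE	TRUE
Mmp9	FPA	ecm_remodeling	0.98	0.90	5.99	7.26	5.4	3.15	TRUE	FALSE	TRUE
Mmp14	FPA	ecm_remodeling	0.56	0.40	16.1	9.21	3.12	0.24	TRUE	TRUE	TRUE
Plat	FPA	ecm_remodeling	0.58	0.22	4.51	2.47	1.73	0.83	TRUE	TRUE	TRUE
Serpine1	FPA	ecm_remodeling	1.00	0.75	12.0	1.83	7.40	3.67	TRUE	TRUE	TRUE
Serpinh1	FPA	ecm_remodeling	0.78	0.41	8.33	7.04	6.78	5.75	TRUE	FALSE	TRUE
Timp1	FPA	ecm_remodeling	0.34	0.51	17.10	10.95	13.0	14.54	FALSE	FALSE	FALSE
Timp2	FPA	ecm_remodeling	0.82	0.35	4.42	1.61	2.18	0.79	TRUE	TRUE	TRUE
Ccl11	FPA	adhesion_inflammation	1.00	0.76	2.62	0.52	1.98	1.89	TRUE	FALSE	TRUE
Ccl12	FPA	adhesion_inflammation	0.88	0.89	17.83	9.11	18.01	24	TRUE	FALSE	TRUE
Ccl3	FPA	adhesion_inflammation	0.86	0.30	16.0	9.25	10.69	4.85	TRUE	FALSE	TRUE
Itgav	FPA	adhesion_inflammation	0.90	0.73	4.32	0.44	1.39	0.38	TRUE	TRUE	TRUE
Itgb1	FPA	adhesion_inflammation	0.93	0.37	6.10	2.10	2.81	0.75	TRUE	TRUE	TRUE
Itgb3	FPA	adhesion_inflammation	0.94	0.30	5.06	2.02	2.56	0.89	TRUE	TRUE	FALSE
Itgb5	FPA	adhesion_inflammation	1.00	0.54	2.34	0.89	1.28	1.01	TRUE	TRUE	FALSE
Cxcr4	FPA	adhesion_inflammation	0.82	0.62	6.10	4.6	1.54	1.26	TRUE	TRUE	FALSE
Il1b	FPA	adhesion_inflammation	0.78	0.23	3.21	1.15	2.19	0.86	TRUE	FALSE	TRUE
Il10	FPA	adhesion_inflammation	0.78	0.48	4.9	0.44	10.61	8.87	TRUE	TRUE	TRUE
Ilk	FPA	adhesion_inflammation	0.88	0.61	5.98	2.11	2.37	1.26	TRUE	TRUE	TRUE
Tnf	FPA	adhesion_inflammation	0.78	0.23	3.2	1.15	2.19	0.86	TRUE	FALSE	TRUE
Faslg	FPA	adhesion_inflammation	0.93	0.47	3.20	0.46	1.36	0.42	TRUE	TRUE	FALSE
Bmp7	FPA	growth_tgfb	0.78	0.71	2.22	0.66	0.6	0.23	TRUE	TRUE	FALSE
Ctgf	FPA	growth_tgfb	0.77	0.24	7.04	2.54	3.0	1.99	TRUE	TRUE	TRUE
Dcn	FPA	growth_tgfb	0.83	0.43	2.25	0.54	1.95	0.34	TRUE	FALSE	TRUE
Edn1	FPA	growth_tgfb	0.80	0.58	4.05	1.28	3.35	1.02	TRUE	FALSE	TRUE
Hgf	FPA	growth_tgfb	0.94	0.55	9.64	4.54	3.75	1.57	TRUE	TRUE	TRUE
Ltbp1	FPA	growth_tgfb	1.04	0.62	3.25	0.62	1.75	0.78	TRUE	TRUE	FALSE
Smad2	FPA	growth_tgfb	0.84	0.55	3.01	0.74	1.60	0.56	TRUE	TRUE	TRUE
Smad4	FPA	growth_tgfb	0.79	0.50	2.80	1.15	1.50	0.89	TRUE	FALSE	FALSE
Smad6	FPA	growth_tgfb	0.75	0.43	1.68	0.50	1.00	0.62	TRUE	TRUE	FALSE
Smad7	FPA	growth_tgfb	0.69	0.49	2.05	0.92	1.56	1.30	TRUE	FALSE	TRUE
Tgfbr1	FPA	growth_tgfb	0.62	0.59	10.7	2.98	1.94	0.64	TRUE	TRUE	TRUE
Tgfbr2	FPA	growth_tgfb	0.55	0.31	4.18	1.82	1.10	0.63	TRUE	TRUE	TRUE
Tgfb1	FPA	growth_tgfb	0.81	0.56	10.8	4.75	3.31	0.65	TRUE	TRUE	TRUE
Tgfb2	FPA	growth_tgfb	0.78	0.67	14.4	11.6	3.04	2.86	TRUE	TRUE	TRUE
Tgfb3	FPA	growth_tgfb	0.66	0.91	7.50	4.96	1.18	0.89	TRUE	TRUE	FALSE
Tgif1	FPA	growth_tgfb	0.85	0.29	2.85	2.00	4.82	0.59	TRUE	TRUE	TRUE
Thbs1	FPA	growth_tgfb	0.74	0.69	24.75	10.9	13.1	4.14	TRUE	TRUE	TRUE
Thbs2	FPA	growth_tgfb	0.91	0.21	9.89	3.62	4.83	4.27	TRUE	TRUE	TRUE
Nfkb1	FPA	transcription_emt	0.83	0.51	3.21	0.59	1.50	0.38	TRUE	TRUE	TRUE
Snai1	FPA	transcription_emt	0.68	0.53	19.33	6.16	9.80	2.30	TRUE	TRUE	TRUE
Sp1	FPA	transcription_emt	0.87	0.49	3.00	0.44	1.60	0.47	TRUE	TRUE	TRUE
Stat1	FPA	transcription_emt	0.81	0.52	2.41	0.75	1.27	0.40	TRUE	TRUE	TRUE
Stat6	FPA	transcription_emt	0.72	0.50	6.67	2.96	2.96	1.54	TRUE	TRUE	TRUE
Jun	FPA	transcription_emt	0.72	0.46	2.54	1.28	0.96	0.86	TRUE	TRUE	FALSE
Myc	FPA	transcription_emt	0.82	0.39	7.53	4.53	7.57	3.82	TRUE	FALSE	TRUE
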