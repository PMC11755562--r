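id	category	parent_id	start	end	sequence	mw	pi	gravy	ai	hydrophilic_pct	aromatic_n	instability	net_charge
BP1	original	NA	2	15	SNKKQSNRLTEQHK	1697.87	10.29	-2.529	27.86	79	1	118.93	3.09
BP2	original	NA	12	23	EQHKLSQGVIGI	1308.50	6.85	-0.183	121.67	42	1	46.85	0.09
BP3	original	NA	20	33	VIGIFGDYAKAHDL	1518.73	5.21	0.514	118.57	21	3	14.07	-0.91
BP4	original	NA	34	47	AVGEVSKLVKKALS	1428.74	9.70	0.471	132.14	43	0	-10.29	2.00
BP5	original	NA	48	60	NEYPQLAFRYRDS	1658.79	6.07	-1.508	37.69	54	3	29.55	0.00
BP6	original	NA	61	74	IKKTEINEALKKID	1642.96	8.43	-0.800	118.57	57	0	18.61	1.00
BP7	original	NA	73	84	IDPDLGGTLFVS	1233.38	3.56	0.683	121.67	25	1	6.09	-2.00
BP8	original	NA	82	93	FVSNSSIKPDGG	1207.31	5.84	-0.350	56.67	50	1	15.86	0.00
BP9	original	NA	89	102	KPDGGIVEVKDDYG	1491.62	4.23	-0.929	69.29	43	1	-12.92	-2.00
BP10	original	NA	103	116	EWRVVLVAEAKHQG	1621.86	6.86	-0.243	104.29	36	2	-1.45	0.09
BP11	original	NA	116	127	GKDIINIRNGLL	1325.57	8.75	0.117	162.50	42	0	36.47	1.00
BP12	original	NA	123	135	RNGLLVGKRGDQD	1427.58	8.75	-1.254	82.31	54	0	27.46	1.00
BP13	original	NA	135	146	DLMAAGNAIERS	1247.39	4.37	-0.050	90.00	42	0	85.61	-1.00
BP14	original	NA	146	157	SHKNISEIANFM	1390.58	6.47	-0.308	73.33	50	2	85.09	0.09
BP15	original	NA	158	170	LSESHFPYVLFLE	1580.80	4.51	0.500	112.31	31	4	45.70	-1.91
BP16	original	NA	170	181	EGSNFLTENISI	1323.42	3.80	-0.092	97.50	50	1	49.31	-2.00
BP17	original	NA	182	193	TRPDGRVVNLEY	1418.57	5.74	-0.942	80.83	42	1	18.93	0.00
BP18	original	NA	194	206	NSGILNRLDRLTA	1442.64	9.60	-0.285	127.69	46	0	11.72	1.00
BP19	original	NA	206	217	AANYGMPINSNL	1264.42	5.57	-0.067	81.67	33	1	38.71	0.00
BP20	original	NA	216	228	NLCINKFVNHKDK	1572.85	9.20	-0.854	82.31	54	2	39.13	2.04
BP21	original	NA	229	242	SIMLQAASIYTQGD	1497.68	3.80	0.271	97.86	36	1	21.12	-1.00
BP22	original	NA	243	252	GREWDSKIMFEIMF	1789.10	4.68	-0.186	55.71	43	3	20.00	-1.00
BP23	original	NA	252	265	FEIMFDISTTSLRV	1658.93	4.37	0.714	104.29	36	2	45.61	-1.00
BP24	original	NA	259	272	STTSLRVLGRDLFE	1593.80	5.79	-0.071	104.29	43	0	23.04	0.00
BP25	original	NA	266	277	LGRDLFEQLTSK	1406.60	6.07	-0.550	97.50	50	1	25.22	0.00
BP7R1	randomized	BP7	NA	NA	VGLILSTGDFDP	1233.38	3.56	0.683	121.67	25	1	15.07	-2.00
BP7R2	randomized	BP7	NA	NA	DGLTPFSDVLGI	1233.38	3.56	0.683	121.67	25	1	18.14	-2.00
BP10R1	randomized	BP10	NA	NA	VEGQELAVKAHRWV	1621.86	6.73	-0.243	104.29	36	2	49.77	0.09
BP10R2	randomized	BP10	NA	NA	AGRKQEVHAVWVEL	1621.86	6.80	-0.243	104.29	36	2	33.89	0.09
BP13R1	randomized	BP13	NA	NA	EALDIAMGRNSA	1247.39	4.37	-0.050	90.00	42	0	19.45	-1.00
BP13R2	randomized	BP13	NA	NA	LAMRGASIADEN	1247.39	4.37	-0.050	90.00	42	0	-18.34	-1.00
BP1.5	staggered	NA	8	19	NRLTEQHKLSQG	1410.55	8.75	-1.658	65.00	58	1	69.98	1.09
BP2.5	staggered	NA	16	27	LSQGVIGIFGDY	1268.43	3.80	0.792	121.67	25	2	18.14	-1.00
BP3.5	staggered	NA	28	39	AKAHDLAVGEVS	1196.33	5.32	0.192	105.83	33	1	-11.27	-0.91
BP4.5	staggered	NA	42	52	VKKALSNEYPQL	1389.61	8.47	-0.700	97.50	50	1	33.10	1.00
BP5.5	staggered	NA	55	66	FRYRDSIKKTEI	1555.80	9.70	-1.233	65.00	58	2	29.87	2.00
BP6.5	staggered	NA	65	79	EALKKIDPDLGG	1255.43	4.56	-0.567	105.83	42	0	-0.98	-1.00
BP7.5	staggered	NA	78	88	GGTLFVSNSSI	1081.19	5.52	0.718	97.27	36	1	30.10	0.00
BP8.5	staggered	NA	86	96	SSIKPDGGIVE	1101.22	4.37	-0.155	97.27	45	0	0.95	-1.00
BP9.5	staggered	NA	97	109	VKDDYGEWRVVL	1478.67	4.56	-0.425	105.00	42	2	-19.12	-1.00
BP10.5	staggered	NA	111	121	EAKHQGKDIIN	1252.39	6.85	-1.327	80.00	55	1	1.37	0.09
BP11.5	staggered	NA	120	131	INIRNGLLVGKR	1352.65	12.01	0.008	154.17	42	0	56.56	3.00
BP12.5	staggered	NA	130	140	KRGDQDLMAAG	1161.30	5.96	-0.945	53.64	45	0	59.74	0.00
BP13.5	staggered	NA	141	151	NAIERSHKNIS	1268.40	8.75	-1.173	80.00	64	1	150.45	1.09
BP14.5	staggered	NA	152	163	EIANFMLSESHF	1424.59	4.51	0.192	73.33	42	2	36.15	-1.91
BP15.5	staggered	NA	165	175	YVLFLEGSNFL	1301.50	4.00	1.064	132.73	27	3	-4.57	-1.00
BP16.5	staggered	NA	176	187	TENISITRPDGR	1358.47	5.74	-1.225	65.00	50	0	71.60	0.00
BP17.5	staggered	NA	188	199	VVNLEYNSGILN	1334.49	4.00	0.333	145.83	42	1	18.14	-1.00
BP18.5	staggered	NA	201	211	LDRLTAANYGM	1224.40	5.84	-0.073	89.09	27	1	-5.48	0.00
BP19.5	staggered	NA	223	234	PINSNLCINK	1383.63	8.57	-0.508	117.00	50	0	32.68	0.95
BP20.5	staggered	NA	237	252	VNHKDKSIMLQA	1426.46	4.03	-1.542	97.50	50	1	48.99	1.09
BP21.5	staggered	NA	246	257	IYTQGDGREWDS	1375.62	4.03	0.291	32.50	50	2	-0.67	-2.00
BP22.5	staggered	NA	212	221	DSKIMFEIMFD	1115.31	8.64	-0.150	70.91	45	2	47.61	-2.00
BP19.5N	deletion_N	BP19.5	212	217	PINSNL	656.74	5.96	-0.183	130.00	50	0	8.33	0.00
BP19.5C	deletion_C	BP19.5	216	221	NLCINK	703.85	8.22	-0.017	130.00	50	0	47.80	0.95
BP6N	short_N	BP6	61	66	IKKTEI	730.90	8.59	-0.500	130.00	50	0	58.38	1.00
BP6M	short_M	BP6	65	70	EINEAL	687.75	3.80	-0.067	146.67	50	0	40.43	-2.00
BP6C	short_C	BP6	69	74	ALKKID	686.85	8.64	-0.200	146.67	50	0	-19.97	1.00
BP7N	short_N	BP7	73	78	IDPDLG	628.68	3.56	-0.117	130.00	33	0	-4.23	-2.00
BP7M	short_M	BP7	76	81	DLGGTL	574.63	3.80	0.433	130.00	17	0	14.75	-1.00
BP7C	short_C	BP7	79	84	GTLFVS	622.72	5.52	1.483	113.33	17	1	-5.82	0.00
BP9N	short_N	BP9	89	94	KPDGGI	585.66	5.84	-0.883	65.00	33	0	-10.38	0.00
BP9M	short_M	BP9	93	98	GIVEVK	643.78	6.00	0.850	161.67	33	0	-24.77	0.00
BP9C	short_C	BP9	97	102	VKDDYG	695.73	4.21	-1.400	48.33	50	1	-10.62	-1.00
BP10N	short_N	BP10	103	108	EWRVVL	800.96	6.10	0.550	161.67	33	1	-16.72	0.00
BP10M	short_M	BP10	107	112	VLVAEA	600.71	4.00	2.050	195.00	17	0	8.33	-1.00
BP10C	short_C	BP10	111	116	EAKHQG	668.71	6.85	-2.117	16.67	50	1	8.33	0.09
BP11N	short_N	BP11	116	121	GKDIIN	658.75	5.84	-0.383	130.00	50	0	-5.82	0.00
BP11M	short_M	BP11	119	124	IINIRN	741.89	9.75	0.333	195.00	50	0	102.13	1.00
BP11C	short_C	BP11	121	127	IRNGLL	684.84	9.75	0.617	195.00	33	0	3.85	1.00
BP12N	short_N	BP12	124	129	NGLLVG	571.67	5.52	1.250	178.33	17	0	-30.87	0.00
BP12M	short_M	BP12	126	132	LVGKRG	628.77	11.00	-0.200	113.33	33	0	20.22	2.00
BP12C	short_C	BP12	130	135	KRGDQD	717.74	5.96	-3.217	0.00	83	0	80.62	0.00
BP13N	short_N	BP13	135	140	DLMAAG	576.67	3.80	0.900	98.33	17	0	28.90	-1.00
BP13M	short_M	BP13	138	143	AAGNAI	515.57	5.57	1.000	115.00	17	0	-5.82	0.00
BP13C	short_C	BP13	141	146	NAIERS	688.74	6.00	-1.000	81.67	67	0	154.80	0.00
BP14N	short_N	BP14	146	151	SHKNIS	684.75	8.49	-1.283	65.00	67	1	121.03	1.09
BP14M	short_M	BP14	149	154	NISEIA	645.71	4.00	0.500	146.67	50	0	145.77	-1.00
BP14C	short_C	BP14	152	157	EIANFM	723.84	4.00	0.667	81.67	33	1	15.38	-1.00
BP15N	short_N	BP15	158	163	LSESHF	718.76	5.24	-0.283	65.00	50	1	55.25	-0.91
BP15M	short_M	BP15	161	166	SHFPYV	748.84	6.46	0.017	48.33	17	2	23.15	0.09
BP15C	short_C	BP15	165	170	YVLFLE	782.93	4.00	1.633	178.33	17	1	8.33	-1.00
BP22N	short_N	BP22	243	248	GREWDS	748.75	4.37	-2.267	0.00	67	1	15.38	-1.00
BP22M	short_M	BP22	245	250	EWDSKI	776.84	4.37	-1.350	65.00	67	1	1.23	-1.00
BP22C	short_C	BP22	247	252	DSKIMF	739.88	5.80	0.167	65.00	50	1	26.28	0.00
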