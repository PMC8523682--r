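block	group	participant	region	mean_z	sd_z	n_voxels
1	patient	1	Left frontal gyrus	2.62	0.28	495
1	patient	1	Left inferior parietal lobule	2.82	0.42	765
1	patient	1	Left inferior frontal gyrus	2.51	0.19	37
1	patient	1	Left middle temporal gyrus	2.55	0.19	27
1	patient	1	Left posterior cingulate cortex	3.07	0.64	982
1	patient	2	Left frontal gyrus	2.83	0.45	906
1	patient	2	Left inferior parietal lobule	2.84	0.46	571
1	patient	2	Left inferior frontal gyrus	2.49	0.20	17
1	patient	2	Left middle temporal gyrus	2.66	0.28	76
1	patient	2	Left posterior cingulate cortex	3.08	0.66	1158
1	patient	3	Left frontal gyrus	3.00	0.57	1309
1	patient	3	Left inferior parietal lobule	3.60	1.01	1604
1	patient	3	Left inferior frontal gyrus	2.77	0.39	112
1	patient	3	Left middle temporal gyrus	2.95	0.55	367
1	patient	3	Left posterior cingulate cortex	3.49	0.93	1618
1	control	1	Left frontal gyrus	3.04	0.66	1015
1	control	1	Left inferior parietal lobule	3.30	0.79	1269
1	control	1	Left inferior frontal gyrus	2.79	0.40	136
1	control	1	Left middle temporal gyrus	3.01	0.66	235
1	control	1	Left posterior cingulate cortex	3.66	1.16	1560
1	control	2	Left frontal gyrus	3.21	0.85	1686
1	control	2	Left inferior parietal lobule	3.51	0.94	1298
1	control	2	Left inferior frontal gyrus	3.06	0.65	281
1	control	2	Left middle temporal gyrus	3.18	0.90	669
1	control	2	Left posterior cingulate cortex	3.86	1.18	1424
1	control	3	Left frontal gyrus	2.75	0.39	403
1	control	3	Left inferior parietal lobule	2.72	0.34	189
1	control	3	Left inferior frontal gyrus	2.75	0.37	16
1	control	3	Left middle temporal gyrus	2.57	0.20	36
1	control	3	Left posterior cingulate cortex	3.12	0.72	601
2	patient	1	Right frontal gyrus	2.71	0.37	412
2	patient	1	Right inferior parietal lobule	2.88	0.50	531
2	patient	1	Right inferior frontal gyrus	2.70	0.30	75
2	patient	1	Right middle temporal gyrus	2.56	0.20	75
2	patient	1	Right posterior cingulate cortex	3.41	1.67	732
2	patient	2	Right frontal gyrus	2.84	0.45	1848
2	patient	2	Right inferior parietal lobule	2.87	0.50	472
2	patient	2	Right inferior frontal gyrus	2.72	0.36	74
2	patient	2	Right middle temporal gyrus	2.76	0.36	155
2	patient	2	Right posterior cingulate cortex	3.36	1.43	1069
2	patient	3	Right frontal gyrus	3.03	0.64	1501
2	patient	3	Right inferior parietal lobule	3.62	1.05	706
2	patient	3	Right inferior frontal gyrus	2.98	0.52	123
2	patient	3	Right middle temporal gyrus	2.98	0.59	175
2	patient	3	Right posterior cingulate cortex	3.86	1.86	1227
2	control	1	Right frontal gyrus	3.13	0.73	1212
2	control	1	Right inferior parietal lobule	3.14	0.74	337
2	control	1	Right inferior frontal gyrus	3.12	0.73	200
2	control	1	Right middle temporal gyrus	2.69	0.33	124
2	control	1	Right posterior cingulate cortex	3.99	1.96	1144
2	control	2	Right frontal gyrus	3.28	0.87	1377
2	control	2	Right inferior parietal lobule	3.33	0.98	420
2	control	2	Right inferior frontal gyrus	3.05	0.67	212
2	control	2	Right middle temporal gyrus	3.10	0.72	171
2	control	2	Right posterior cingulate cortex	4.60	3.04	1225
2	control	3	Right frontal gyrus	2.66	0.31	205
2	control	3	Right inferior parietal lobule	2.65	0.25	150
2	control	3	Right inferior frontal gyrus	2.36	0.08	3
2	control	3	Right middle temporal gyrus	2.49	0.14	28
2	control	3	Right posterior cingulate cortex	3.53	1.70	542
3	patient	1	Left frontal gyrus	2.94	0.59	1076
3	patient	1	Left inferior parietal lobule	3.60	0.97	1758
3	patient	1	Left inferior frontal gyrus	2.68	0.34	280
3	patient	1	Left middle temporal gyrus	2.78	0.40	325
3	patient	1	Left posterior cingulate cortex	4.00	2.25	1472
3	patient	2	Left frontal gyrus	3.03	0.60	1475
3	patient	2	Left inferior parietal lobule	3.00	0.56	585
3	patient	2	Left inferior frontal gyrus	2.87	0.41	35
3	patient	2	Left middle temporal gyrus	2.76	0.41	85
3	patient	2	Left posterior cingulate cortex	3.34	0.96	1703
3	patient	3	Left frontal gyrus	3.00	0.56	791
3	patient	3	Left inferior parietal lobule	3.19	0.80	935
3	patient	3	Left inferior frontal gyrus	2.75	0.53	85
3	patient	3	Left middle temporal gyrus	2.99	0.52	362
3	patient	3	Left posterior cingulate cortex	3.29	1.30	1271
3	control	1	Left frontal gyrus	3.27	0.92	1480
3	control	1	Left inferior parietal lobule	3.83	1.32	1850
3	control	1	Left inferior frontal gyrus	3.14	0.66	239
3	control	1	Left middle temporal gyrus	3.20	0.88	373
3	control	1	Left posterior cingulate cortex	4.22	2.37	1736
3	control	2	Left frontal gyrus	3.58	1.19	3703
3	control	2	Left inferior parietal lobule	3.58	0.95	1530
3	control	2	Left inferior frontal gyrus	3.47	0.95	1054
3	control	2	Left middle temporal gyrus	3.09	0.74	945
3	control	2	Left posterior cingulate cortex	4.55	3.49	1691
3	control	3	Left frontal gyrus	2.78	0.44	1121
3	control	3	Left inferior parietal lobule	3.00	0.57	907
3	control	3	Left inferior frontal gyrus	2.63	0.28	236
3	control	3	Left middle temporal gyrus	2.82	0.49	576
3	control	3	Left posterior cingulate cortex	3.28	2.04	443
4	patient	1	Right frontal gyrus	2.79	0.46	701
4	patient	1	Right inferior parietal lobule	3.12	0.70	808
4	patient	1	Right inferior frontal gyrus	2.75	0.36	124
4	patient	1	Right middle temporal gyrus	2.68	0.31	140
4	patient	1	Right posterior cingulate cortex	3.79	1.26	828
4	patient	2	Right frontal gyrus	3.03	0.60	1792
4	patient	2	Right inferior parietal lobule	3.01	0.63	188
4	patient	2	Right inferior frontal gyrus	2.60	0.29	12
4	patient	2	Right middle temporal gyrus	2.58	0.24	43
4	patient	2	Right posterior cingulate cortex	3.56	0.96	1545
4	patient	3	Right frontal gyrus	2.80	0.48	573
4	patient	3	Right inferior parietal lobule	2.92	0.49	169
4	patient	3	Right inferior frontal gyrus	2.53	0.20	30
4	patient	3	Right middle temporal gyrus	2.60	0.30	47
4	patient	3	Right posterior cingulate cortex	3.31	0.80	1038
4	control	1	Right frontal gyrus	3.27	0.90	1473
4	control	1	Right inferior parietal lobule	3.56	1.10	568
4	control	1	Right inferior frontal gyrus	3.15	0.74	255
4	control	1	Right middle temporal gyrus	2.98	0.63	255
4	control	1	Right posterior cingulate cortex	4.19	1.65	1128
4	control	2	Right frontal gyrus	3.58	1.09	2671
4	control	2	Right inferior parietal lobule	3.54	1.09	608
4	control	2	Right inferior frontal gyrus	3.25	0.79	552
4	control	2	Right middle temporal gyrus	2.97	0.57	290
4	control	2	Right posterior cingulate cortex	4.21	1.69	1422
4	control	3	Right frontal gyrus	2.78	0.45	610
4	control	3	Right inferior parietal lobule	2.92	0.54	277
4	control	3	Right inferior frontal gyrus	2.75	0.38	133
4	control	3	Right middle temporal gyrus	2.64	0.29	171
4	control	3	Right posterior cingulate cortex	2.88	0.57	247
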