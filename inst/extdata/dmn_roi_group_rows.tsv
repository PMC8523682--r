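block	group	region	printed_mean	printed_sd
1	patient	Left frontal gyrus	2.82	0.19
1	patient	Left inferior parietal lobule	3.09	0.44
1	patient	Left inferior frontal gyrus	2.59	0.16
1	patient	Left middle temporal gyrus	2.72	0.21
1	patient	Left posterior cingulate cortex	3.21	0.24
1	control	Left frontal gyrus	3.00	0.23
1	control	Left inferior parietal lobule	3.18	0.41
1	control	Left inferior frontal gyrus	2.87	0.17
1	control	Left middle temporal gyrus	2.92	0.31
1	control	Left posterior cingulate cortex	3.55	0.38
2	patient	Right frontal gyrus	2.86	0.16
2	patient	Right inferior parietal lobule	3.12	0.43
2	patient	Right inferior frontal gyrus	2.80	0.16
2	patient	Right middle temporal gyrus	2.77	0.21
2	patient	Right posterior cingulate cortex	3.54	0.27
2	control	Right frontal gyrus	3.02	0.32
2	control	Right inferior parietal lobule	3.04	0.35
2	control	Right inferior frontal gyrus	2.85	0.42
2	control	Right middle temporal gyrus	2.76	0.31
2	control	Right posterior cingulate cortex	4.04	0.54
3	patient	Left frontal gyrus	2.99	0.05
3	patient	Left inferior parietal lobule	3.27	0.31
3	patient	Left inferior frontal gyrus	2.77	0.09
3	patient	Left middle temporal gyrus	2.84	0.13
3	patient	Left posterior cingulate cortex	3.55	0.40
3	control	Left frontal gyrus	3.21	0.40
3	control	Left inferior parietal lobule	3.47	0.42
3	control	Left inferior frontal gyrus	3.08	0.42
3	control	Left middle temporal gyrus	3.04	0.19
3	control	Left posterior cingulate cortex	4.01	0.66
4	patient	Right frontal gyrus	2.87	0.13
4	patient	Right inferior parietal lobule	3.02	0.10
4	patient	Right inferior frontal gyrus	2.62	0.11
4	patient	Right middle temporal gyrus	2.62	0.06
4	patient	Right posterior cingulate cortex	3.55	0.24
4	control	Right frontal gyrus	3.21	0.40
4	control	Right inferior parietal lobule	3.34	0.36
4	control	Right inferior frontal gyrus	3.05	0.27
4	control	Right middle temporal gyrus	2.87	0.20
4	control	Right posterior cingulate cortex	3.76	0.76
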