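patient	sen	spe	ppv	fallout	f_score	seg_auc_fba	seg_auc_fba_ada	seg_auc_fba_fs_ada	channel_auc	n_electrodes	n_soz	G
Pt1	23.70	96.26	25.00	3.74	0.24	0.64	0.77	0.79	0.90	60	3	5
Pt2	45.93	86.64	43.01	13.36	0.44	0.71	0.78	0.83	0.79	50	9	5
Pt3	37.46	82.83	30.37	17.18	0.34	0.52	0.52	0.63	0.71	42	7	3
Pt4	42.96	84.07	19.69	15.93	0.27	0.66	0.73	0.75	0.79	36	3	5
Pt5	79.25	97.50	62.57	2.50	0.70	0.93	0.95	0.97	0.96	60	3	3
Pt6	54.82	96.42	58.96	3.58	0.57	0.90	0.94	0.97	0.94	70	6	4
Pt7	49.02	83.76	27.71	16.24	0.35	0.65	0.70	0.70	0.81	71	8	6
Pt8	88.52	98.54	71.34	1.46	0.79	0.96	0.98	0.99	0.99	76	3	3
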