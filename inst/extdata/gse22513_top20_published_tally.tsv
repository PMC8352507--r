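feature	gene_symbol	anonymized	selected	times_selected	perfect_trees	all_zero	all_positive	all_negative	non_monotone	two_neuron_perfect	one_neuron_perfect	enumerable_solutions	unique_solution
205363_at	BBOX1	a14811	1	160	160	0	160	0	0	160	160	160	160
207781_s_at	ZNF711	a17223	1	170	170	0	168	0	0	170	170	170	170
210015_s_at	MAP2	a19421	1	125	125	0	124	0	0	125	125	125	125
210212_x_at	CMC4	a19615	1	133	133	0	132	0	0	133	133	133	133
214913_at	ADAMTS3	a24209	1	144	144	0	143	0	0	144	144	144	144
221641_s_at	ACOT9	a30923	1	138	138	0	137	0	0	138	138	138	138
225036_at	TOMM5	a34294	1	159	159	0	158	0	0	159	159	159	159
227462_at	ERAP2	a36718	1	140	140	0	0	140	0	140	140	140	140
227676_at	FAM3D	a36931	1	138	138	0	138	0	0	138	138	138	138
228053_s_at	TOMM5	a37308	1	146	146	0	146	0	0	146	146	146	146
228382_at	OTULIN	a37637	1	149	149	0	147	0	0	149	149	149	149
241359_at	TLCD2	a50609	1	144	144	0	143	0	0	144	144	144	144
1553875_s_at	ZSCAN10	a1172	0	155	155	0	0	0	155	0	0	155	155
1556008_a_at	-	a2731	0	174	174	0	0	0	174	0	0	174	174
200618_at	LASP1	a10067	0	177	177	0	0	0	177	0	0	177	177
200979_at	PDHA1	a10428	0	182	182	0	0	0	182	0	0	182	182
201220_x_at	CTBP2	a10669	0	164	164	0	0	0	164	0	0	164	164
202000_at	NDUFA6	a11449	0	159	159	0	0	0	159	0	0	159	159
202018_s_at	LTF	a11467	0	168	168	0	0	0	168	0	0	168	168
202382_s_at	GNPDA1	a11831	0	173	173	0	0	0	173	0	0	173	173
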