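locus	start	end
SYN-GENE01	1	206
SYN-GENE02	207	277
SYN-GENE03	278	557
SYN-GENE04	558	597
SYN-GENE05	598	1732
SYN-GENE06	1733	2493
SYN-GENE07	2494	2853
SYN-GENE08	2854	3121
SYN-GENE09	3122	3181
SYN-GENE10	3182	3399
SYN-GENE11	3400	4427
SYN-GENE12	4428	4893
SYN-GENE13	4894	5017
SYN-GENE14	5018	5477
SYN-GENE15	5478	5751
SYN-GENE16	5752	6171
SYN-GENE17	6172	6542
SYN-GENE18	6543	6608
SYN-GENE19	6609	6759
SYN-GENE20	6760	6923
SYN-GENE21	6924	7270
SYN-GENE22	7271	7301
SYN-GENE23	7302	7656
SYN-GENE24	7657	9172
SYN-GENE25	9173	9387
SYN-GENE26	9388	11434
SYN-GENE27	11435	11689
SYN-GENE28	11690	12185
SYN-GENE29	12186	12275
SYN-GENE30	12276	12507
SYN-GENE31	12508	12903
SYN-GENE32	12904	13352
SYN-GENE33	13353	14396
SYN-GENE34	14397	15135
SYN-GENE35	15136	16093
SYN-GENE36	16094	16388
SYN-GENE37	16389	16569
SYN-SITE01	191	555
SYN-SITE02	713	865
SYN-SITE03	1582	2050
SYN-SITE04	2449	2893
SYN-SITE05	2791	3262
SYN-SITE06	3232	3349
SYN-SITE07	3340	3660
SYN-SITE08	4534	4958
SYN-SITE09	4840	5323
SYN-SITE10	5620	6108
SYN-SITE11	5629	6040
SYN-SITE12	5774	5914
SYN-SITE13	5987	6094
SYN-SITE14	6445	6600
SYN-SITE15	6863	7200
SYN-SITE16	6999	7063
SYN-SITE17	7228	7377
SYN-SITE18	7478	7626
SYN-SITE19	7551	7639
SYN-SITE20	8808	9042
SYN-SITE21	9071	9299
SYN-SITE22	10548	10665
SYN-SITE23	10823	11414
SYN-SITE24	10938	11502
SYN-SITE25	11093	11459
SYN-SITE26	11255	11397
SYN-SITE27	11257	11317
SYN-SITE28	11387	11938
SYN-SITE29	11585	11834
SYN-SITE30	11820	12270
SYN-SITE31	12517	12713
SYN-SITE32	12573	13013
SYN-SITE33	13727	13910
SYN-SITE34	14832	15083
SYN-SITE35	14906	15436
SYN-SITE36	15014	15457
SYN-SITE37	15221	15351
SYN-SITE38	15350	15608
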