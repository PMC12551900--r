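category	<50	50-59	60-69	70-79	>=80
Lack of efficacy	104	953	3761	6303	7094
General complications	70	536	2508	5203	5082
Infection	15	118	535	1064	1062
CNS	42	443	1932	3680	3803
OPH/ENT	11	99	556	1358	1202
Respiratory	18	168	673	1589	1750
Musculoskeletal	66	537	2079	3543	3485
Vascular	48	409	2045	4164	3972
Endocrine	21	211	921	1254	739
Gastro intestinal	82	564	2570	4566	4118
Kidney/Urology	16	224	1078	1901	1808
Skin	47	291	1269	2071	1558
Others	72	523	2019	3556	4023
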