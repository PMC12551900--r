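category	G1	G2	G3	G4	G5
Lack of efficacy	12251	783	138	4720	323
General complications	10329	678	225	1977	190
Infection	1518	217	57	929	73
CNS	7677	496	162	1403	162
OPH/ENT	2574	171	39	412	30
Respiratory	2485	239	82	1274	118
Musculoskeletal	7103	450	183	1774	200
Vascular	6573	682	189	2946	248
Endocrine	2039	258	51	754	44
Gastro intestinal	8339	523	193	2633	212
Kidney/Urology	2736	270	111	1765	145
Skin	3487	776	139	763	71
Others	6028	666	256	3126	117
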