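block	level	G1	G2	G3	G4	G5
Serious	Serious	17355	2221	579	9523	624
Serious	Non-serious	8454	1110	154	4771	65
Case priority	Direct	845	955	20	5654	5
Case priority	Expedited	14877	1722	559	6236	529
Case priority	Non-Expedited	10087	654	154	2404	155
Reporter type	Consumer	18089	1032	368	3895	155
Reporter type	Healthcare Professional	7586	2019	365	9591	530
Reporter type	Not Specified	134	280	0	808	4
Age	<50	127	9	8	90	7
Age	50-59	1248	107	46	765	37
Age	60-69	5140	640	156	3267	165
Age	70-79	9525	1311	252	5280	283
Age	>=80	9769	1264	271	4892	197
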