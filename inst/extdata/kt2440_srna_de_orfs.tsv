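no	gene_name	orf_id	cog_code	product	direction
1	PP_0042	PP_0042	-	Hypothetical protein	up
2	PP_0608	PP_0608	-	Hypothetical protein	up
3	oprH	PP_1185	M	Outer membrane protein H1	up
4	phoP	PP_1186	T	Two component transcriptional regulator	up
5	lon-1	PP_1443	O	ATP-dependent protease La	up
6	PP_1487	PP_1487	S	Hypothetical protein	up
7	ibpA	PP_1982	O	Heat shock protein Hsp20	up
8	PP_2197	PP_2197	-	Hypothetical protein	up
9	PP_2198	PP_2198	G	Glucose sorbosone dehydrogenase	up
10	PP_2285	PP_2285	-	Hypothetical protein	up
11	rbsB	PP_2454	G	Monosaccharide-transporting ATPase	up
12	PP_2520	PP_2520	-	Hypothetical protein	up
13	PP_2909	PP_2909	-	Hypothetical protein	up
14	PP_3172	PP_3172	L	Group II intron-encoding maturase	up
15	PP_3305	PP_3305	P	TerC family membrane protein	up
16	PP_3328	PP_3328	R	Ring-cleaving dioxygenase	up
17	PP_3381	PP_3381	-	ISPpu9, transposase	up
18	PP_3678	PP_3678	-	Hypothetical protein	up
19	PP_4025	PP_4025	L	ISPpu15, transposase Orf2	up
20	PP_4092	PP_4092	L	ISPpu15, transposase Orf1	up
21	bkdAA	PP_4401	C	3-Methyl-2-oxobutanoate dehydrogenase	up
22	bkdAB	PP_4402	C	2-Oxoisovalerate dehydrogenase subunit beta	up
23	PP_4504	PP_4504	U	Hypothetical protein	up
24	grpE	PP_4728	O	Heat shock protein GrpE	up
25	hslV	PP_5000	O	ATP-dependent protease peptidase subunit	up
26	hslU	PP_5001	O	ATP-dependent protease ATP-binding subunit HslU	up
27	PP_5403	PP_5403	-	Hypothetical protein	up
28	PP_0526	PP_0526	L	ISPpu10, transposase	down
29	PP_0700	PP_0700	P	FecR anti-FecI sigma factor	down
30	PP_4070	PP_4070	P	Hypothetical protein	down
31	exbB	PP_5306	U	Ferric siderophore transport system protein ExbB	down
32	exbD	PP_5307	U	Biopolymer transport protein ExbD	down
33	tonB	PP_5308	M	TonB family protein	down
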