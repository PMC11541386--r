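id	label	phase	delta
R1	hydroxylation	I	+O
R2	dihydroxylation	I	+O2
R3	trihydroxylation	I	+O3
R4	dehydrogenation	I	-H2
R5	bis-dehydrogenation	I	-H4
R6	hydrogenation	I	+H2
R7	bis-hydrogenation	I	+H4
R8	oxidation to carbonyl	I	+O -H2
R9	oxidation to carboxylic acid	I	+O2 -H2
R10	demethylation	I	-CH2
R11	bis-demethylation	I	-C2H4
R12	depropylation	I	-C3H6
R13	hydration	I	+H2O
R14	dehydration	I	-H2O
R15	decarboxylation	I	-CO2
R16	deacetylation	I	-C2H2O
R17	formylation	I	+CO
R18	oxidative ring cleavage	I	+H2O2
R19	demethylation to hydroxyl	I	-CH2 +O
R20	epoxidation	I	+O
R21	carbonyl reduction	I	+H2
R22	deethylation	I	-C2H4
R23	methylation	II	+CH2
R24	dimethylation	II	+C2H4
R25	acetylation	II	+C2H2O
R26	propionylation	II	+C3H4O
R27	sulfation	II	+SO3
R28	phosphorylation	II	+HPO3
R29	glucuronic acid conjugation	II	+C6H8O6
R30	pentose conjugation	II	+C5H8O4
R31	deoxyhexose conjugation	II	+C6H10O4
R32	N-acetylhexosamine conjugation	II	+C8H13NO5
R33	malonic acid conjugation	II	+C3H2O3
R34	succinic acid conjugation	II	+C4H4O3
R35	glutathione conjugation	II	+C10H15N3O6S
R36	cysteine conjugation	II	+C3H5NOS
R37	cysteinylglycine conjugation	II	+C5H8N2O2S
R38	N-acetylcysteine conjugation	II	+C5H7NO2S
R39	taurine conjugation	II	+C2H5NO2S
R40	glycine conjugation	II	+C2H3NO
R41	alanine conjugation	II	+C3H5NO
R42	serine conjugation	II	+C3H5NO2
R43	threonine conjugation	II	+C4H7NO2
R44	valine conjugation	II	+C5H9NO
R45	leucine conjugation	II	+C6H11NO
R46	isoleucine conjugation	II	+C6H11NO
R47	proline conjugation	II	+C5H7NO
R48	methionine conjugation	II	+C5H9NOS
R49	phenylalanine conjugation	II	+C9H9NO
R50	tyrosine conjugation	II	+C9H9NO2
R51	tryptophan conjugation	II	+C11H10N2O
R52	aspartic acid conjugation	II	+C4H5NO3
R53	glutamic acid conjugation	II	+C5H7NO3
R54	asparagine conjugation	II	+C4H6N2O2
R55	glutamine conjugation	II	+C5H8N2O2
R56	lysine conjugation	II	+C6H12N2O
R57	histidine conjugation	II	+C6H7N3O
R58	arginine conjugation	II	+C6H12N4O
R59	ornithine conjugation	II	+C5H10N2O
R60	pterin conjugation	II	+C6H3N5O
R61	methylsalicylate conjugation	II	+C8H6O2
R62	glucopyranosyloxy conjugation	II	+C6H10O5
R63	glucose conjugation	II	+C6H10O5
R64	galactose conjugation	II	+C6H10O5
R65	glucose conjugation + hydroxylation	combination	+C6H10O5 +O
R66	glucose conjugation + dehydrogenation	combination	+C6H10O5 -H2
R67	glucose conjugation + hydrogenation	combination	+C6H10O5 +H2
R68	glucose conjugation + demethylation	combination	+C6H10O5 -CH2
R69	glucose conjugation + hydration	combination	+C6H10O5 +H2O
R70	glucose conjugation + decarboxylation	combination	+C6H10O5 -CO2
R71	glucose conjugation + glucose conjugation	combination	+C6H10O5 +C6H10O5
R72	glucose conjugation + malonic acid conjugation	combination	+C6H10O5 +C3H2O3
R73	glucuronic acid conjugation + hydroxylation	combination	+C6H8O6 +O
R74	glucuronic acid conjugation + dehydrogenation	combination	+C6H8O6 -H2
R75	glucuronic acid conjugation + hydrogenation	combination	+C6H8O6 +H2
R76	glucuronic acid conjugation + demethylation	combination	+C6H8O6 -CH2
R77	glucuronic acid conjugation + hydration	combination	+C6H8O6 +H2O
R78	glucuronic acid conjugation + decarboxylation	combination	+C6H8O6 -CO2
R79	glucuronic acid conjugation + glucose conjugation	combination	+C6H8O6 +C6H10O5
R80	glucuronic acid conjugation + malonic acid conjugation	combination	+C6H8O6 +C3H2O3
R81	malonic acid conjugation + hydroxylation	combination	+C3H2O3 +O
R82	malonic acid conjugation + dehydrogenation	combination	+C3H2O3 -H2
R83	malonic acid conjugation + hydrogenation	combination	+C3H2O3 +H2
R84	malonic acid conjugation + demethylation	combination	+C3H2O3 -CH2
R85	malonic acid conjugation + hydration	combination	+C3H2O3 +H2O
R86	malonic acid conjugation + decarboxylation	combination	+C3H2O3 -CO2
R87	malonic acid conjugation + glucose conjugation	combination	+C3H2O3 +C6H10O5
R88	malonic acid conjugation + malonic acid conjugation	combination	+C3H2O3 +C3H2O3
R89	acetylation + hydroxylation	combination	+C2H2O +O
R90	acetylation + dehydrogenation	combination	+C2H2O -H2
R91	acetylation + hydrogenation	combination	+C2H2O +H2
R92	acetylation + demethylation	combination	+C2H2O -CH2
R93	acetylation + hydration	combination	+C2H2O +H2O
R94	acetylation + decarboxylation	combination	+C2H2O -CO2
R95	acetylation + glucose conjugation	combination	+C2H2O +C6H10O5
R96	acetylation + malonic acid conjugation	combination	+C2H2O +C3H2O3
R97	sulfation + hydroxylation	combination	+SO3 +O
R98	sulfation + dehydrogenation	combination	+SO3 -H2
R99	sulfation + hydrogenation	combination	+SO3 +H2
R100	sulfation + demethylation	combination	+SO3 -CH2
R101	sulfation + hydration	combination	+SO3 +H2O
R102	sulfation + decarboxylation	combination	+SO3 -CO2
R103	sulfation + glucose conjugation	combination	+SO3 +C6H10O5
R104	sulfation + malonic acid conjugation	combination	+SO3 +C3H2O3
R105	methylation + hydroxylation	combination	+CH2 +O
R106	methylation + dehydrogenation	combination	+CH2 -H2
R107	methylation + hydrogenation	combination	+CH2 +H2
R108	methylation + demethylation	combination	+CH2 -CH2
R109	methylation + hydration	combination	+CH2 +H2O
R110	methylation + decarboxylation	combination	+CH2 -CO2
R111	methylation + glucose conjugation	combination	+CH2 +C6H10O5
R112	methylation + malonic acid conjugation	combination	+CH2 +C3H2O3
R113	glycine conjugation + hydroxylation	combination	+C2H3NO +O
R114	glycine conjugation + dehydrogenation	combination	+C2H3NO -H2
R115	glycine conjugation + hydrogenation	combination	+C2H3NO +H2
R116	glycine conjugation + demethylation	combination	+C2H3NO -CH2
R117	glycine conjugation + hydration	combination	+C2H3NO +H2O
R118	glycine conjugation + decarboxylation	combination	+C2H3NO -CO2
R119	glycine conjugation + glucose conjugation	combination	+C2H3NO +C6H10O5
R120	glycine conjugation + malonic acid conjugation	combination	+C2H3NO +C3H2O3
R121	glutamine conjugation + hydroxylation	combination	+C5H8N2O2 +O
R122	glutamine conjugation + dehydrogenation	combination	+C5H8N2O2 -H2
R123	glutamine conjugation + hydrogenation	combination	+C5H8N2O2 +H2
R124	glutamine conjugation + demethylation	combination	+C5H8N2O2 -CH2
R125	glutamine conjugation + hydration	combination	+C5H8N2O2 +H2O
R126	glutamine conjugation + decarboxylation	combination	+C5H8N2O2 -CO2
R127	glutamine conjugation + glucose conjugation	combination	+C5H8N2O2 +C6H10O5
R128	glutamine conjugation + malonic acid conjugation	combination	+C5H8N2O2 +C3H2O3
R129	cysteine conjugation + hydroxylation	combination	+C3H5NOS +O
R130	cysteine conjugation + dehydrogenation	combination	+C3H5NOS -H2
R131	cysteine conjugation + hydrogenation	combination	+C3H5NOS +H2
R132	cysteine conjugation + demethylation	combination	+C3H5NOS -CH2
R133	cysteine conjugation + hydration	combination	+C3H5NOS +H2O
R134	cysteine conjugation + decarboxylation	combination	+C3H5NOS -CO2
R135	cysteine conjugation + glucose conjugation	combination	+C3H5NOS +C6H10O5
R136	cysteine conjugation + malonic acid conjugation	combination	+C3H5NOS +C3H2O3
R137	pterin conjugation + hydroxylation	combination	+C6H3N5O +O
R138	pterin conjugation + dehydrogenation	combination	+C6H3N5O -H2
R139	pterin conjugation + hydrogenation	combination	+C6H3N5O +H2
R140	pterin conjugation + demethylation	combination	+C6H3N5O -CH2
R141	pterin conjugation + hydration	combination	+C6H3N5O +H2O
R142	pterin conjugation + decarboxylation	combination	+C6H3N5O -CO2
R143	pterin conjugation + glucose conjugation	combination	+C6H3N5O +C6H10O5
R144	pterin conjugation + malonic acid conjugation	combination	+C6H3N5O +C3H2O3
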