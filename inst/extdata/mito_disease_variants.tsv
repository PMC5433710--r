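notation	gene	codon_printed	protein_change	status	phenotype	codon_source
m.8561C>G	mt-ATP6	12	P12R	reported	Ataxia with neuropathy, DM, SNHL and hypogonadism	printed
m.8741T>G	mt-ATP6	72	L72R	reported	MILS	printed
m.8851T>C	mt-ATP6	109	W109R	reported	BSN	printed
m.8969G>A	mt-ATP6	148	S148N	reported	MLASA	printed
m.9016A>G	mt-ATP6	164	I164V	reported	LHON	printed
m.9035T>C	mt-ATP6	170	L170P	reported	Ataxia syndromes	printed
m.9191T>C	mt-ATP6	222	L222P	reported	LD	printed
m.8528T>C	mt-ATP8	55	W55R	reported	Mitochondrial complex V deficiency	printed
m.5935A>G	mt-CO1	11	N11S	reported	PC	printed
m.6277G>A	mt-CO1	125	G125D	reported	CC	printed
m.6328C>T	mt-CO1	142	S142F	reported	EXIT	printed
m.6489C>A	mt-CO1	196	L196I	reported	Therapy-Resistant Epilepsy	printed
m.6597C>A	mt-CO1	232	Q232K	reported	MELAS-like syndrome	printed
m.6955G>A	mt-CO1	351	G351D	reported	Mild EXIT and moderate mental retardation	printed
m.7023G>A	mt-CO1	374	V374M	reported	MELAS-like syndrome	printed
m.7041G>A	mt-CO1	380	V380I	reported	PC	printed
m.7305A>C	mt-CO1	468	M468L	reported	PC	printed
m.7637G>A	mt-CO2	18	E18K	reported	PD risk factor	printed
m.7671T>A	mt-CO2	29	M29K	reported	MM	printed
m.7877A>C	mt-CO2	98	K98Q	reported	PEG	printed
m.7989T>C	mt-CO2	135	L135P	reported	Rhabdomyolysis	printed
m.9267G>C	mt-CO3	21	A21P	reported	MIDD	printed
m.9544G>A	mt-CO3	113	G113E	reported	Sporadic bilateral optic neuropathy	printed
m.9789T>C	mt-CO3	195	S195P	reported	Myopathy	printed
m.14841A>G	mt-CYB	32	N32S	reported	LHON	printed
m.14846G>A	mt-CYB	34	G34S	reported	EXIT	printed
m.15024G>A	mt-CYB	93	C93Y	reported	Possible DEAF modifier	printed
m.15092G>A	mt-CYB	116	G116S	reported	MELAS	printed
m.15197T>C	mt-CYB	151	S151P	reported	EXIT	printed
m.15209T>C	mt-CYB	155	Y155H	reported	Prader-Willi syndrome	printed
m.15243G>A	mt-CYB	166	G166E	reported	HCM	printed
m.15615G>A	mt-CYB	290	G290D	reported	EXIT, and Antimycin resistance	printed
m.15635T>C	mt-CYB	297	S297P	reported	Polyvisceral failure	printed
m.15699G>C	mt-CYB	318	R318P	reported	Muscle Weakness SNHL and Migraine	printed
m.15762G>A	mt-CYB	339	G339E	reported	MM	printed
m.3380G>A	mt-ND1	25	R25Q	reported	MELAS	printed
m.3388C>A	mt-ND1	28	L28M	reported	Maternally Inherited Nonsyndromic Deafness	printed
m.3418A>G	mt-ND1	38	N38D	reported	AMegL	printed
m.3481G>A	mt-ND1	59	E59K	reported	MELAS / Progressive Encephalomyopathy	printed
m.3688G>A	mt-ND1	128	A128T	reported	LD	printed
m.3946G>A	mt-ND1	214	E214K	reported	MELAS	printed
m.3949T>C	mt-ND1	215	Y215H	reported	MELAS	printed
m.3959G>A	mt-ND1	218	G218D	reported	MELAS	printed
m.3995A>G	mt-ND1	230	N230S	reported	MELAS	printed
m.4160T>C	mt-ND1	286	M286P	reported	LHON	printed
m.4633C>G	mt-ND2	55	A55G	reported	LHON	printed
m.5244G>A	mt-ND2	259	G259S	reported	LHON	printed
m.10254G>A	mt-ND3	66	D66N	reported	LD	printed
m.11232T>C	mt-ND4	160	L160P	reported	CPEO	printed
m.11375A>C	mt-ND4	206	K206Q	reported	sCJD	printed
m.10543A>G	mt-ND4L	25	H25R	reported	LHON	printed
m.10591T>G	mt-ND4L	41	F41C	reported	LHON	printed
m.12770A>G	mt-ND5	145	E145G	reported	MELAS	printed
m.12782T>G	mt-ND5	149	I149S	reported	LHON	printed
m.12848C>T	mt-ND5	171	A171V	reported	LHON	printed
m.13042G>A	mt-ND5	236	A236T	reported	Optic neuropathy, retinopathy, and LD	printed
m.13045A>C	mt-ND5	237	M237L	reported	MELAS, LHON, and Leigh overlap syndrome	printed
m.13063G>A	mt-ND5	243	V243I	reported	Adult-onset Encephalopathy and Ataxia	printed
m.13084A>T	mt-ND5	250	S250C	reported	MELAS, LD	printed
m.13094T>C	mt-ND5	253	V253A	reported	Ataxia with PEO, MELAS, LD, myoclonus and fatigue	printed
m.13379A>C	mt-ND5	348	H348S	reported	LHON	printed
m.13511A>T	mt-ND5	392	K392M	reported	Leigh-like syndrome	printed
m.13730G>A	mt-ND5	465	G465E	reported	LHON	printed
m.14091A>T	mt-ND5	585	K585N	reported	Developmental delay, seizure, hearing loss and diabetes	printed
m.14600G>A	mt-ND6	25	P25L	reported	LD with optic atrophy	printed
m.14498T>C	mt-ND6	59	Y59C	reported	LHON	printed
m.14453G>A	mt-ND6	74	A74V	reported	MELAS	printed
m.14439G>A	mt-ND6	79	P79S	reported	Mitochondrial Respiratory Chain Disorder	printed
m.14430A>G	mt-ND6	82	W82R	reported	TC	printed
m.8836A>G	mt-ATP6	104	M104V	reported	LHON	printed
m.8890A>G	mt-ATP6	122	K122E	reported	Juvenile-onset metabolic syndrome	printed
m.6267G>A	mt-CO1	122	A122T	reported	PC	printed
m.6285G>A	mt-CO1	128	V128I	reported	PC	printed
m.6721T>C	mt-CO1	273	M273T	reported	Acquired Idiopathic Sideroblastic Anemia	printed
m.6742T>C	mt-CO1	280	I280T	reported	Acquired Idiopathic Sideroblastic Anemia	printed
m.7080T>C	mt-CO1	393	F393L	reported	PC	printed
m.7587T>C	mt-CO2	1	M1T	reported	MELAS	printed
m.9438G>A	mt-CO3	78	G78S	reported	LHON	printed
m.9957T>C	mt-CO3	251	F251L	reported	PEM / MELAS / NAION	printed
m.4648T>C	mt-ND2	60	F60S	reported	PEG	printed
m.4852T>A	mt-ND2	128	L128Q	reported	LHON	printed
m.10086A>G	mt-ND3	10	N10D	reported	Hypertensive end-stage renal disease	printed
m.13271T>C	mt-ND5	312	L312P	reported	EXIT	printed
m.10158T>C	mt-ND3	34	S34P	confirmed	LD	printed
m.10191T>C	mt-ND3	45	S45P	confirmed	LD	printed
m.8528T>C	mt-ATP6	1	M1T	confirmed	Neuromuscular disorder and infantile cardiomyopathy	printed
m.14482C>A	mt-ND6	64	M64I	confirmed	LHON	printed
m.14482C>G	mt-ND6	64	M64I	confirmed	LHON	printed
m.14484T>C	mt-ND6	64	M64V	confirmed	LHON	printed
m.3635G>A	mt-ND1	110	S110N	confirmed	LHON	printed
m.3700G>A	mt-ND1	132	A132T	confirmed	LHON	printed
m.8993T>C	mt-ATP6	156		confirmed	NARP / LD / MILS	derived
m.15579A>G	mt-CYB	278		confirmed	Multisystem disorder and EXIT	derived
m.3496G>T	mt-ND1	64	A64S	reported	LHON	printed
m.5913G>A	mt-CO1	4	D4N	reported	PC and hypertension	printed
m.12811T>C	mt-ND5	159	Y159H	reported	LHON	printed
m.6150G>A	mt-CO1	83		reported	PC	derived
m.8021A>G	mt-CO2	146		reported	Mitochondrial disease	derived
m.15077G>A	mt-CYB	111		reported	EXIT	derived
m.3421G>A	mt-ND1	39		reported	MELAS	derived
m.4659G>A	mt-ND2	64		reported	Mitochondrial disease	derived
m.10398A>G	mt-ND3	114		reported	PD protective factor / disease association	derived
m.11253T>C	mt-ND4	165		reported	LHON	derived
m.13528A>G	mt-ND5	398		reported	LHON	derived
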