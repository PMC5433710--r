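property_id	property_name	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
kd_hydropathy	Hydropathy (Kyte-Doolittle)	1.8	-4.5	-3.5	-3.5	2.5	-3.5	-3.5	-0.4	-3.2	4.5	3.8	-3.9	1.9	2.8	-1.6	-0.8	-0.7	-0.9	-1.3	4.2
polarity_grantham	Polarity (Grantham)	8.1	10.5	11.6	13.0	5.5	10.5	12.3	9.0	10.4	5.2	4.9	11.3	5.7	5.2	8.0	9.2	8.6	5.4	6.2	5.9
composition_grantham	Composition (Grantham)	0	0.65	1.33	1.38	2.75	0.89	0.92	0.74	0.58	0	0	0.33	0	0	0.39	1.42	0.71	0.13	0.20	0
molecular_volume	Molecular volume (Grantham)	31	124	56	54	55	85	83	3	96	111	111	119	105	132	32.5	32	61	170	136	84
molecular_weight	Residue molecular weight	89.1	174.2	132.1	133.1	121.2	146.2	147.1	75.1	155.2	131.2	131.2	146.2	149.2	165.2	115.1	105.1	119.1	204.2	181.2	117.1
isoelectric_point	Isoelectric point	6.00	10.76	5.41	2.77	5.07	5.65	3.22	5.97	7.59	6.02	5.98	9.74	5.74	5.48	6.30	5.68	5.60	5.89	5.66	5.96
bulkiness	Bulkiness (Zimmerman)	11.50	14.28	12.82	11.68	13.46	14.45	13.57	3.40	13.69	21.40	21.40	15.71	16.25	19.80	17.43	9.47	15.77	21.67	18.03	21.57
polarity_zimmerman	Polarity (Zimmerman)	0	52.00	3.38	49.70	1.48	3.53	49.90	0	51.60	0.13	0.13	49.50	1.43	0.35	1.58	1.67	1.66	2.10	1.61	0.13
helix_propensity	Alpha-helix propensity (Chou-Fasman)	1.42	0.98	0.67	1.01	0.70	1.11	1.51	0.57	1.00	1.08	1.21	1.16	1.45	1.13	0.57	0.77	0.83	1.08	0.69	1.06
sheet_propensity	Beta-sheet propensity (Chou-Fasman)	0.83	0.93	0.89	0.54	1.19	1.10	0.37	0.75	0.87	1.60	1.30	0.74	1.05	1.38	0.55	0.75	1.19	1.37	1.47	1.70
turn_propensity	Reverse-turn propensity (Chou-Fasman)	0.66	0.95	1.56	1.46	1.19	0.98	0.74	1.56	0.95	0.47	0.59	1.01	0.60	0.60	1.52	1.43	0.96	0.96	1.14	0.50
refractivity	Refractive index increment (Jones)	4.34	26.66	13.28	12.00	35.77	17.56	17.26	0.00	21.81	19.06	18.78	21.29	21.64	29.40	10.93	6.35	11.01	42.53	31.53	13.92
hydrophilicity	Hydrophilicity (Hopp-Woods)	-0.5	3.0	0.2	3.0	-1.0	0.2	3.0	0.0	-0.5	-1.8	-1.8	3.0	-1.3	-2.5	0.0	0.3	-0.4	-3.4	-2.3	-1.5
vdw_volume	Normalized van der Waals volume (Fauchere)	1.00	6.13	2.95	2.78	2.43	3.95	3.78	0.00	4.66	4.00	4.00	4.77	4.43	5.89	2.72	1.60	2.60	8.08	6.47	3.00
polarizability	Polarizability (Charton)	0.046	0.291	0.134	0.105	0.128	0.180	0.151	0.000	0.230	0.186	0.186	0.219	0.221	0.290	0.131	0.062	0.108	0.409	0.298	0.140
max_asa	Maximum solvent-accessible surface area	129	274	195	193	167	225	223	104	224	197	201	236	224	240	159	155	172	285	263	174
hydrophobicity_fp	Octanol-water hydrophobicity (Fauchere-Pliska)	0.31	-1.01	-0.60	-0.77	1.54	-0.22	-0.64	0.00	0.13	1.80	1.70	-0.99	1.23	1.79	0.72	-0.04	0.26	2.25	0.96	1.22
hydrophobicity_eis	Consensus hydrophobicity (Eisenberg)	0.62	-2.53	-0.78	-0.90	0.29	-0.85	-0.74	0.48	-0.40	1.38	1.06	-1.50	0.64	1.19	0.12	-0.18	-0.05	0.81	0.26	1.08
helix_cost	Helix formation free-energy cost (Pace-Scholtz)	0.00	0.21	0.65	0.69	0.68	0.39	0.40	1.00	0.61	0.41	0.21	0.26	0.24	0.54	3.16	0.50	0.66	0.49	0.53	0.61
transfer_energy	Surface-to-interior transfer energy (Janin)	0.3	-1.4	-0.5	-0.6	0.9	-0.7	-0.7	0.3	-0.1	0.7	0.5	-1.8	0.4	0.5	-0.3	-0.1	-0.2	0.3	-0.4	0.6
net_charge	Net side-chain charge at pH 7	0	1	0	-1	0	0	-1	0	0	0	0	1	0	0	0	0	0	0	0	0
sc_carbons	Side-chain carbon atoms	1	4	2	2	1	3	3	0	4	4	4	4	3	7	3	1	2	9	7	3
sc_nitrogens	Side-chain nitrogen atoms	0	3	1	0	0	1	0	0	2	0	0	1	0	0	0	0	0	1	0	0
sc_oxygens	Side-chain oxygen atoms	0	0	1	2	0	1	2	0	0	0	0	0	0	0	0	1	1	0	1	0
sc_sulfurs	Side-chain sulfur atoms	0	0	0	0	1	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0
sc_heavy_atoms	Side-chain heavy atoms	1	7	4	4	2	5	5	0	6	4	4	5	4	7	3	2	3	10	8	3
hbond_donors	Side-chain hydrogen-bond donor hydrogens	0	5	2	0	1	2	0	0	1	0	0	3	0	0	0	1	1	1	1	0
hbond_acceptors	Side-chain hydrogen-bond acceptor groups	0	0	1	2	0	1	2	0	1	0	0	0	0	0	0	1	1	0	1	0
aromatic_atoms	Aromatic ring atoms	0	0	0	0	0	0	0	0	5	0	0	0	0	6	0	0	0	9	6	0
rotatable_bonds	Rotatable side-chain bonds	0	4	2	2	1	3	3	0	2	2	2	4	3	2	0	1	1	2	2	1
pka_distance	Side-chain pKa distance from neutrality	0	5.5	0	3.35	1.3	0	2.75	0	1.0	0	0	3.5	0	0	0	0	0	0	3.1	0
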