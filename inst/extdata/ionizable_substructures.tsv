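# Ionizable-substructure rule table (38 rules, priority 1 = highest).
# Columns: name<TAB>priority<TAB>SMARTS<TAB>site_indices<TAB>mu1<TAB>sigma1[<TAB>mu2<TAB>sigma2]
# site_indices are 1-based positions of the ionizable atom(s) in the SMARTS
# pattern; two (mu, sigma) pairs mark a diprotic site (first-then-second
# dissociation). SMARTS match both the protonated and deprotonated drawn
# forms so that the engine can assign absolute states regardless of input.
# Parameters are reconstructed estimates of per-moiety experimental pKa
# means/standard deviations (aqueous, near room temperature); the phenol
# entry carries the published 7.07 / 3.28. The nitro sentinel -1000 forces
# deprotonation of nitro oxygens at any pH.
nitro	1	[NX3+](=[OX1])[OX1-]	3	-1000.0	0.0
azide	2	[$([NX2H1]),$([NX1-])]=[NX2+]=[NX1-]	1	4.65	0.31
sulfate	3	[SX4](=[OX1])(=[OX1])([OX2][#6])[$([OX2H1]),$([OX1-])]	5	-2.36	1.30
sulfonate	4	[SX4](=[OX1])(=[OX1])([#6])[$([OX2H1]),$([OX1-])]	5	-1.82	1.41
sulfinic_acid	5	[SX3](=[OX1])([#6])[$([OX2H1]),$([OX1-])]	4	1.80	0.70
phosphate_diester	6	[PX4](=[OX1])([OX2][#6])([OX2][#6])[$([OX2H1]),$([OX1-])]	6	1.47	0.88
phosphate	7	[PX4](=[OX1])([OX2,OX1-])([$([OX2H1]),$([OX1-])])[$([OX2H1]),$([OX1-])]	4,5	1.88	0.89	6.75	1.02
phosphonate_ester	8	[PX4](=[OX1])([OX2][#6])([#6])[$([OX2H1]),$([OX1-])]	6	2.02	0.67
phosphinic_acid	9	[PX4](=[OX1])([#6])([#6])[$([OX2H1]),$([OX1-])]	5	2.70	0.62
phosphonate	10	[PX4](=[OX1])([#6])([$([OX2H1]),$([OX1-])])[$([OX2H1]),$([OX1-])]	4,5	2.18	0.87	7.54	1.08
hydroxamic_acid	11	[CX3](=[OX1])[NX3][$([OX2H1]),$([OX1-])]	4	9.21	0.92
thioic_acid	12	[CX3](=[OX1])[$([SX2H1]),$([SX1-])]	3	3.32	0.60
peracid	13	[CX3](=[OX1])[OX2][$([OX2H1]),$([OX1-])]	4	8.20	0.40
benzoic_acid	14	[c][CX3](=[OX1])[$([OX2H1]),$([OX1-])]	4	3.97	0.87
carboxylic_acid	15	[CX3](=[OX1])[$([OX2H1]),$([OX1-])]	3	3.40	1.10
imide	16	[CX3](=[OX1])[$([NX3H1]),$([NX2-])][CX3](=[OX1])	3	8.50	1.50
amide_electronegative	17	[CX3](=[OX1])[NX3][#7,#8,F,Cl,Br,I]	3	12.00	1.50
amide	18	[CX3](=[OX1])[NX3]	3	16.50	1.00
sulfonamide	19	[SX4](=[OX1])(=[OX1])[$([NX3H2]),$([NX3H1]),$([NX2-])]	4	10.10	2.16
tetrazole	20	[$([nX3H1]),$([nX2-])]1[nX2][nX2][nX2]c1	1	4.89	0.80
aromatic_n_protonated	21	[$([nX3H1+0]),$([nX2-])]	1	14.52	2.63
aromatic_n_unprotonated	22	[$([nX2H0+0]),$([nX3H1+])]	1	4.80	2.60
thiophenol	23	[c][$([SX2H1]),$([SX1-])]	2	6.62	1.33
thiol	24	[#6X4][$([SX2H1]),$([SX1-])]	2	9.12	1.33
phenol	25	[c][$([OX2H1]),$([OX1-])]	2	7.07	3.28
peroxide	26	[#6][OX2][$([OX2H1]),$([OX1-])]	3	11.80	0.90
enol_conjugated_ketone	27	[OX1]=[CX3][CX3]=[CX3][$([OX2H1]),$([OX1-])]	5	5.60	1.60
vinyl_alcohol	28	[CX3]=[CX3][$([OX2H1]),$([OX1-])]	3	10.00	1.30
alcohol	29	[#6X4][$([OX2H1]),$([OX1-])]	2	14.78	1.32
guanidine	30	[NX3][CX3](=[$([NX2+0]),$([NX3+])])[NX3]	3	12.55	1.07
amidine	31	[#6][CX3](=[$([NX2+0]),$([NX3+])])[NX3]	3	11.18	1.28
aniline_primary	32	[c][$([NX3H2+0]),$([NX4H3+])]	2	4.70	1.10
aniline_secondary	33	[c][$([NX3H1+0]),$([NX4H2+])][#6X4]	2	4.95	1.22
aniline_tertiary	34	[c][$([NX3H0+0]),$([NX4H1+])]([#6X4])[#6X4]	2	5.10	1.32
hydroxylamine	35	[OX2][$([NX3H2+0]),$([NX4H3+])]	2	5.20	0.85
amine_primary	36	[#6X4][$([NX3H2+0]),$([NX4H3+])]	2	9.99	2.40
amine_secondary	37	[#6X4][$([NX3H1+0]),$([NX4H2+])][#6X4]	2	10.47	2.49
amine_tertiary	38	[#6X4][$([NX3H0+0]),$([NX4H1+])]([#6X4])[#6X4]	2	9.76	2.20
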