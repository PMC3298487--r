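# label: SPFLI-up
# direction: up
# Genes up-regulated by JTX treatment in the large intestine of IQI SPF mice.
probe_id	gene_name	symbol	entrez	fold_change	p_value
93956_at	interferon-induced protein with tetratricopeptide repeats 3	Ifit3	15959	4.71	0.092
95024_at	ubiquitin specific peptidase 18	Usp18	24110	4.50	0.020
98822_at	ISG15 ubiquitin-like modifier	G1p2	53606	4.06	0.077
100981_at	interferon-induced protein with tetratricopeptide repeats 1	Ifit1	15957	3.84	0.033
103066_at	thymidylate kinase family LPS-inducible member	Tyki	22169	3.72	0.012
103639_at	interferon-induced protein with tetratricopeptide repeats 2	Ifit2	15958	3.37	0.036
104669_at	interferon regulatory factor 7	Irf7	54123	2.87	0.069
98410_at	interferon inducible GTPase 2	Iigp2	54396	2.49	0.021
104177_at	radical S-adenosyl methionine domain containing 2	Rsad2	58185	2.45	0.033
103335_at	lectin, galactose binding, soluble 9	Lgals9	16859	2.40	0.038
93442_at	zinc finger protein 316	Zfp316	54201	1.97	0.065
161357_r_at	glutathione S-transferase, mu 2	Gstm2	14863	1.90	0.049
102867_at	TEA domain family member 4	Tead4	21679	1.82	0.009
100909_at	protease, serine, 8 (prostasin)	Prss8	76560	1.81	0.066
103657_i_at	metal response element binding transcription factor 2	Mtf2	17765	1.73	0.081
102879_s_at	Fc receptor, IgG, high affinity I	Fcgr1	14129	1.71	0.053
92560_g_at	vascular cell adhesion molecule 1	Vcam1	22329	1.69	0.036
95037_at	cyclin-dependent kinase 9 (CDC2-related kinase)	Cdk9	107951	1.69	0.086
104708_at	Transducin (beta)-like 1 X-linked	Tbl1x	21372	1.67	0.082
103884_at	ATP binding domain 1 family, member C	Atpbd1c	68080	1.66	0.061
99446_at	membrane-spanning 4-domains, subfamily A, member 1	Ms4a1	12482	1.63	0.083
103634_at	interferon dependent positive acting transcription factor 3 gamma	Isgf3g	16391	1.58	0.068
93464_at	A kinase (PRKA) anchor protein (yotiao) 9	Akap9	100986	1.54	0.088
92384_at	xeroderma pigmentosum, complementation group A	Xpa	22590	1.54	0.051
100472_at	enabled homolog (Drosophila)	Enah	13800	1.52	0.067
103080_at	SAM domain and HD domain, 1	Samhd1	56045	1.51	0.045
102808_at	Sodium channel, voltage-gated, type I, beta	Scn1b	20266	1.51	0.074
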