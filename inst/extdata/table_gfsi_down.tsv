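# label: GFSI-down
# direction: down
# Genes down-regulated by JTX treatment in the small intestine of IQI germ-free mice.
probe_id	gene_name	symbol	entrez	fold_change	p_value
103842_at	DEAD (Asp-Glu-Ala-Asp) box polypeptide 3, Y-linked	Ddx3y	26900	0.01	0.006
103674_f_at	eukaryotic translation initiation factor 2, subunit 3, structural gene Y-linked	Eif2s3y	26908	0.03	0.022
95024_at	ubiquitin specific peptidase 18	Usp18	24110	0.11	0.003
100981_at	interferon-induced protein with tetratricopeptide repeats 1	Ifit1	15957	0.15	0.010
93956_at	interferon-induced protein with tetratricopeptide repeats 3	Ifit3	15959	0.17	0.009
160933_at	interferon gamma induced GTPase	Igtp	16145	0.19	0.000
98822_at	ISG15 ubiquitin-like modifier	G1p2	53606	0.20	0.035
92718_at	interferon, alpha-inducible protein 27	Ifi27	76933	0.24	0.019
104750_at	interferon gamma inducible protein 47	Ifi47	15953	0.25	0.009
98030_at	tripartite motif protein 30	Trim30	20128	0.25	0.003
104177_at	radical S-adenosyl methionine domain containing 2	Rsad2	58185	0.27	0.004
102906_at	T-cell specific GTPase	Tgtp	21822	0.29	0.000
92472_f_at	schlafen 2	Slfn2	20556	0.31	0.004
98410_at	interferon inducible GTPase 2	Iigp2	54396	0.32	0.007
103066_at	thymidylate kinase family LPS-inducible member	Tyki	22169	0.36	0.024
97409_at	immunity-related GTPase family, M	Irgm	15944	0.36	0.021
103446_at	interferon induced with helicase C domain 1	Ifih1	71586	0.39	0.010
102699_at	myxovirus (influenza virus) resistance 2	Mx2	17858	0.42	0.012
93078_at	lymphocyte antigen 6 complex, locus A	Ly6a	110454	0.43	0.030
160668_at	opioid growth factor receptor	Ogfr	72075	0.44	0.006
103254_at	TRAF type zinc finger domain containing 1	Trafd1	231712	0.44	0.043
103202_at	guanylate nucleotide binding protein 4	Gbp4	55932	0.44	0.013
101465_at	signal transducer and activator of transcription 1	Stat1	20846	0.44	0.021
103634_at	interferon dependent positive acting transcription factor 3 gamma	Isgf3g	16391	0.47	0.006
103035_at	transporter 1, ATP-binding cassette, sub-family B (MDR/TAP)	Tap1	21354	0.48	0.027
103080_at	SAM domain and HD domain, 1	Samhd1	56045	0.50	0.016
103812_at	chloride channel calcium activated 1	Clca1	12722	0.50	0.019
160847_at	tRNA nucleotidyl transferase, CCA-adding, 1	Trnt1	70047	0.52	0.014
102873_at	transporter 2, ATP-binding cassette, sub-family B (MDR/TAP)	Tap2	21355	0.57	0.037
100475_at	tripartite motif protein 25	Trim25	217069	0.58	0.025
98283_at	5'-3' exoribonuclease 1	Xrn1	24127	0.61	0.005
96151_at	Molybdenum cofactor sulfurase	Mocos	68591	0.61	0.010
102812_i_at	ubiquitin-activating enzyme E1-domain containing 1	Ube1dc1	66663	0.62	0.003
94461_at	pre-B-cell colony-enhancing factor 1	Pbef1	59027	0.62	0.030
95886_g_at	CREB binding protein	Crebbp	12914	0.63	0.012
103673_at	complement component 2 (within H-2S)	C2	12263	0.63	0.013
97921_at	Agrin	Agrn	11603	0.63	0.043
102279_at	ubiquitin-activating enzyme E1-like	Ube1l	74153	0.64	0.013
104070_at	p300/CBP-associated factor	Pcaf	18519	0.64	0.002
96157_at	zinc finger protein 91	Zfp91	109910	0.65	0.009
94192_at	ganglioside-induced differentiation-associated-protein 10	Gdap10	14546	0.66	0.049
103025_at	Moloney leukemia virus 10	Mov10	17454	0.67	0.042
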