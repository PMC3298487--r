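# label: BALBLI-down
# direction: down
# Genes down-regulated by JTX treatment in the large intestine of BALB/c SPF mice.
probe_id	gene_name	symbol	entrez	fold_change	p_value
160841_at	D site albumin promoter binding protein	Dbp	13170	0.27	0.029201
104177_at	radical S-adenosyl methionine domain containing 2	Rsad2	58185	0.39	0.012171
95024_at	ubiquitin specific peptidase 18	Usp18	24110	0.41	0.016077
160933_at	interferon gamma induced GTPase	Igtp	16145	0.46	0.052323
100981_at	interferon-induced protein with tetratricopeptide repeats 1	Ifit1	15957	0.48	0.030177
98822_at	ISG15 ubiquitin-like modifier	G1p2	53606	0.49	0.053022
103202_at	guanylate nucleotide binding protein 4	Gbp4	55932	0.52	0.018878
98410_at	interferon inducible GTPase 2	Iigp2	54396	0.55	0.008083
93956_at	interferon-induced protein with tetratricopeptide repeats 3	Ifit3	15959	0.56	0.053353
103634_at	interferon dependent positive acting transcription factor 3 gamma	Isgf3g	16391	0.56	0.009681
101561_at	metallothionein 2	Mt2	17750	0.59	0.001359
93573_at	metallothionein 1	Mt1	17748	0.61	0.00141
161964_r_at	Protein kinase C, zeta	Prkcz	18762	0.61	0.066851
103335_at	lectin, galactose binding, soluble 9	Lgals9	16859	0.62	0.024207
99076_at	Nuclear receptor subfamily 1, group D, member 2	Nr1d2	353187	0.63	0.049119
93085_at	proteosome (prosome, macropain) subunit, beta type 9	Psmb9	16912	0.63	0.00915
160208_at	splicing factor 3b, subunit 3	Sf3b3	101943	0.63	0.043591
104750_at	interferon gamma inducible protein 47	Ifi47	15953	0.64	0.053488
161287_f_at	MYB binding protein (P160) 1a	Mybbp1a	18432	0.64	0.014332
93178_at	neuronal guanine nucleotide exchange factor	Ngef	53972	0.65	0.017146
92315_at	schlafen 4	Slfn4	20558	0.65	0.053414
104669_at	interferon regulatory factor 7	Irf7	54123	0.67	0.017792
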