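# label: GFLI-down
# direction: down
# Genes down-regulated by JTX treatment in the large intestine of IQI germ-free mice.
probe_id	gene_name	symbol	entrez	fold_change	p_value
103842_at	DEAD (Asp-Glu-Ala-Asp) box polypeptide 3, Y-linked	Ddx3y	26900	0.02	0.004
103674_f_at	eukaryotic translation initiation factor 2, subunit 3, structural gene Y-linked	Eif2s3y	26908	0.07	0.008
103639_at	interferon-induced protein with tetratricopeptide repeats 2	Ifit2	15958	0.09	0.015
104750_at	interferon gamma inducible protein 47	Ifi47	15953	0.12	0.002
100981_at	interferon-induced protein with tetratricopeptide repeats 1	Ifit1	15957	0.18	0.021
104177_at	radical S-adenosyl methionine domain containing 2	Rsad2	58185	0.20	0.012
102906_at	T-cell specific GTPase	Tgtp	21822	0.24	0.034
96764_at	interferon inducible GTPase 1	Iigp1	60440	0.27	0.001
103202_at	guanylate nucleotide binding protein 4	Gbp4	55932	0.29	0.045
160933_at	interferon gamma induced GTPase	Igtp	16145	0.30	0.004
98410_at	interferon inducible GTPase 2	Iigp2	54396	0.36	0.014
104669_at	interferon regulatory factor 7	Irf7	54123	0.38	0.034
103335_at	lectin, galactose binding, soluble 9	Lgals9	16859	0.38	0.039
100030_at	uridine phosphorylase 1	Upp1	22271	0.40	0.015
103634_at	interferon dependent positive acting transcription factor 3 gamma	Isgf3g	16391	0.44	0.040
92715_at	ubiquitin D	Ubd	24108	0.44	0.011
93085_at	proteosome (prosome, macropain) subunit, beta type 9 (large multifunctional peptidase 2)	Psmb9	16912	0.47	0.036
102791_at	proteosome (prosome, macropain) subunit, beta type 8 (large multifunctional peptidase 7)	Psmb8	16913	0.49	0.014
103446_at	interferon induced with helicase C domain 1	Ifih1	71586	0.50	0.038
101465_at	Signal transducer and activator of transcription 1	Stat1	20846	0.51	0.026
103035_at	transporter 1, ATP-binding cassette, sub-family B (MDR/TAP)	Tap1	21354	0.54	0.035
97950_at	xanthine dehydrogenase	Xdh	22436	0.54	0.010
104597_at	guanylate nucleotide binding protein 2	Gbp2	14469	0.56	0.025
97507_at	lectin, galactoside-binding, soluble, 3 binding protein	Lgals3bp	19039	0.60	0.047
102200_at	aquaporin 8	Aqp8	11833	0.60	0.019
102873_at	transporter 2, ATP-binding cassette, sub-family B (MDR/TAP)	Tap2	21355	0.60	0.015
103254_at	TRAF type zinc finger domain containing 1	Trafd1	231712	0.60	0.011
103892_r_at	elongation factor RNA polymerase II 2	Ell2	192657	0.62	0.039
99475_at	suppressor of cytokine signaling 2	Socs2	216233	0.66	0.024
92672_at	GNAS (guanine nucleotide binding protein, alpha stimulating) complex locus	Gnas	14683	0.67	0.010
98472_at	histocompatibility 2, T region locus 23///RIKEN cDNA C920025E04 gene	H2-T23	15040	0.67	0.007
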