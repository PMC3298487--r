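# Published module-match counts per promoter set for the four top-ranked
# two-motif frameworks, plus genome-wide background over all annotated
# mouse promoters (set = "background"). matches = total module matches,
# sequences = number of promoter sequences scanned.
module	set	matches	sequences
V$IRFF-V$IRFF	SPFLI-up	31	26
V$IRFF-V$IRFF	BALB-down	33	26
V$IRFF-V$IRFF	GFLI-down	55	45
V$IRFF-V$IRFF	GFSI-down	67	55
V$IRFF-V$IRFF	background	19374	51460
V$IRFF-V$MYT1	SPFLI-up	14	26
V$IRFF-V$MYT1	BALB-down	12	26
V$IRFF-V$MYT1	GFLI-down	24	45
V$IRFF-V$MYT1	GFSI-down	30	55
V$IRFF-V$MYT1	background	13423	51460
V$CREB-V$GCMF	SPFLI-up	4	26
V$CREB-V$GCMF	BALB-down	6	26
V$CREB-V$GCMF	GFLI-down	10	45
V$CREB-V$GCMF	GFSI-down	14	55
V$CREB-V$GCMF	background	4675	51460
V$ETSF-V$DEAF	SPFLI-up	3	26
V$ETSF-V$DEAF	BALB-down	8	26
V$ETSF-V$DEAF	GFLI-down	17	45
V$ETSF-V$DEAF	GFSI-down	17	55
V$ETSF-V$DEAF	background	6540	51460
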