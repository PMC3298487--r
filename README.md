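# ifnmodmap

Differential-expression filtering, cross-condition gene-list concordance,
and promoter-module enrichment for interferon signatures — an R package
that re-implements, end to end and with tested synthetic data, the
microarray-to-cis-regulation inference chain used to study how the herbal
medicine juzentaihoto (JTX) modulates the type-1 interferon machinery
(the ISGF3–IRF7 cascade) in mouse intestine.

## Who this is for

Transcriptomics and regulatory-genomics analysts who work with
MAS5-style processed array tables (linear signal plus Present/Marginal/
Absent detection calls) and want a reproducible, scriptable version of
the classical rule-based analysis: call/intensity filtering, Welch's
t-test with fold-change thresholds, gene-list set algebra across
conditions, position-weight-matrix scanning with two-motif framework
("promoter module") matching, an appearance-ratio enrichment statistic,
and the ΔΔCt / time-course arithmetic used in qPCR validation.

## The statistics at the core

* **Gene lists.** Probe sets are retained when at least one sample group
  has ≥ 2 non-absent calls and the larger comparison-group mean signal is
  ≥ 50; a gene is listed when Welch's t on log2 signals gives p < 0.1 and
  the linear fold change FC = mean(treated)/mean(control) satisfies
  FC > 1.5 (up) or FC < 0.67 (down). No multiple-testing correction, by
  protocol.
* **Concordance.** For lists *A*, *B*: overlap |A ∩ B| keyed by probe-set
  id, membership counts per gene across lists, percentages relative to
  the smaller list.
* **Appearance ratio.** For a two-motif framework *M* and a promoter set
  with *s* sequences carrying *k* module matches, r = k/s (can exceed 1).
  Across gene lists the ratios r₁…rₙ are summarised as mean ± sample SD
  and tested against the genome-wide background ratio r₀ with a
  one-sample t: t = (r̄ − r₀)/(s/√n), df = n − 1.
* **Framework discovery.** Motif pairs recurring with consistent spacing
  are ranked by the binomial tail probability of their promoter support
  under a background model with exact per-motif match probabilities
  (dynamic programming over the score distribution).
* **Validation.** Fold change = efficiency^(−ΔΔCt) with a designated
  reference gene; time-to-peak = argmax of the sampled group means with
  right-censoring at the last time point; Student's pooled t and
  protected Fisher-LSD comparisons.

## Worked example

The four published condition gene lists and the module-count matrix ship
as plain-text fixtures:

```r
library(ifnmodmap)

lists <- jtx_gene_lists()
vapply(lists, nrow, 0L)
#>    SPFLI-up BALBLI-down   GFLI-down   GFSI-down
#>          27          22          31          42

# interferon-stimulated genes shared by the germ-free large-intestine
# down list and the SPF up list -- the directional flip
intersect_lists(lists[["GFLI-down"]], lists[["SPFLI-up"]])$symbol
#> [1] "Ifit2"  "Ifit1"  "Rsad2"  "Iigp2"  "Irf7"   "Lgals9" "Isgf3g"

# the twelve-gene core signature present in >= 3 of the four lists
length(shared_genes(lists, min_lists = 3))
#> [1] 12

# appearance-ratio enrichment of the four candidate frameworks
enrichment_table(jtx_module_counts())
#>          module n_lists mean_ratio   sd_ratio background_ratio statistic      p_value
#> 1 V$IRFF-V$IRFF       4  1.2254856 0.03203336       0.37648659 53.007181 1.478803e-05
#> 2 V$IRFF-V$MYT1       4  0.5196970 0.03908932       0.26084337 13.244212 9.301442e-04
#> 3 V$CREB-V$GCMF       4  0.2153458 0.04322031       0.09084726  5.761111 1.039306e-02
#> 4 V$ETSF-V$DEAF       4  0.2774864 0.11291087       0.12708900  2.664002 7.607839e-02
```

The first row is the tandem IRF-site framework: on average 1.23 matches
per promoter across the four affected gene lists against 0.38 in all
annotated mouse promoters — the enrichment that singles out tandem
IRF-family sites as the candidate primary target of the treatment.

Everything upstream of the fixtures can be run on synthetic data with
known truth:

```r
res <- run_pipeline("synthetic", seed = 1)
res$summary$list_sizes        # per-condition up/down list sizes
res$summary$enrichment_mean   # planted-module appearance ratio
```

Motif scanning works on any FASTA through `read_promoter_fasta()`,
`scan_pwm()`, `match_module()` and `write_bed()`; the packaged IRF-like
matrix is a clearly labelled synthetic stand-in (vendor matrix libraries
are proprietary).

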