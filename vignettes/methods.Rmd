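---
title: "From detection calls to promoter modules: the methods behind ifnmodmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From detection calls to promoter modules: the methods behind ifnmodmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnmodmap)
```

## What this package computes

`ifnmodmap` re-implements, as a tested and reusable chain, an inference
route that runs from MAS5-style microarray tables to a cis-regulatory
hypothesis about the type-1 interferon machinery. The biological setting is
a two-week oral treatment with the ten-herb Kampo medicine juzentaihoto
(JTX) in mice that differ in strain (IQI vs BALB/c) and in microbiota
status (specific-pathogen-free vs germ-free), profiled in the large and
small intestine with control and treated groups of three arrays each. The
chain has four stages:

1. **Gene-list derivation** (`call_de()` and friends): detection-call
   filter, intensity floor, Welch's t-test, strict fold-change thresholds.
2. **Cross-condition concordance** (`intersect_lists()`,
   `membership_counts()`, `concordance_report()`): set algebra over the
   per-condition lists, which exposes the striking directional flip — the
   same interferon-stimulated genes rise in IQI-SPF mice and fall in
   BALB/c and germ-free animals.
3. **Promoter-module analysis** (`scan_pwm()`, `match_module()`,
   `discover_frameworks()`): position-weight-matrix scanning and two-motif
   "framework" matching over promoter sequences, summarised by the
   appearance-ratio enrichment statistic (`enrichment_summary()`).
4. **Validation arithmetic** (`ddct_fold_change()`, `time_to_peak()`,
   `compare_groups()`, `fisher_lsd()`): the ΔΔCt quantification and the
   time-course summaries used for the qPCR/ELISA follow-up experiments.

A synthetic-data module (`simulate_expression()`, `simulate_promoters()`)
generates inputs with known ground truth so that every stage is exercised
without any external download. This is an analysis package: its interface
is the exported functions plus `scripts/acceptance.R`; there is no shell
executable.

## The gene-list derivation rules

A probe set enters a condition's comparison only if it passes two
screens, then two decision rules:

* **Detection calls.** The operative published rule is an exclusion: a
  probe set with 2 or 3 Absent calls per group *in every group* is
  dropped. We implement exactly the complement — retained if and only if
  at least one group has at least `min_present_per_group` (default 2)
  non-absent calls. The source describes the same rule a second time in
  present-call terms that do not agree with the first phrasing once
  Marginal calls exist; because the exclusion sentence is the operative
  one, Marginal counts as "not absent" by default, and the stricter
  Present-only reading is available via `filter_params(marginal =
  "absent")`. A test enumerates all 729 pattern pairs of
  `{P,M,A}^3 x {P,M,A}^3` against a brute-force transcription of the
  exclusion sentence.
* **Intensity floor.** The published analysis dropped probe sets with
  signals below 50 for reproducibility reasons, without stating the exact
  scope. We retain a probe when the *larger* of the two comparison-group
  means reaches the floor, so a gene strongly induced or silenced by
  treatment can never be discarded for being low on the other side. The
  scope is configurable.
* **Welch's t-test, p < 0.1.** The test scale is not stated in the
  source; we default to `log2(signal + 1)` (variance stabilisation) and
  offer linear for sensitivity analysis. There is deliberately **no
  multiple-testing correction** anywhere: the lenient screen was part of
  the published protocol, with fold change carrying the specificity
  burden, and we reproduce that protocol rather than "improve" it.
* **Fold change.** Linear group-mean ratio (treated / control), strictly
  greater than 1.5 for the up list and strictly less than 0.67 for the
  down list. Up lists are sorted by descending and down lists by
  ascending fold change, matching the printed table order. Zero-variance
  probes with unequal means are excluded with a warning rather than
  crashing the chain.

A statistical caveat the package documents rather than hides: with three
replicates per group, Welch's t is conservative. Its true null rejection
rate at the nominal 0.1 level is about 0.079 (the Welch–Satterthwaite
degrees of freedom drop below the pooled test's), so on null simulations
the p-screen passes roughly 8%, not 10%, of eligible probes. The test
suite asserts this measured behaviour.

## Concordance arithmetic

Lists are joined by probe-set id by default — unambiguous on one array
design — with a symbol join available because results are narrated by
symbol. Overlap percentages are reported relative to the smaller list of
a pair (the "15 of 31 genes" phrasing). Two documented numerical notes:
the narrated "8 genes" shared between the SPF-up and BALB/c-down lists
recomputes to 9 probe sets from the printed tables (Iigp2/98410_at is in
both but was not marked); and "more than 3 lists" only yields the printed
twelve-gene core signature under the ≥ 3 reading, so the threshold is an
explicit parameter (`shared_genes(lists, min_lists = 3)`), with ≥ 4
giving the four genes common to all lists.

## PWM scanning and frameworks

The vendor tools used for the original promoter analysis (and their
matrix library) are proprietary, so this package provides a transparent
reconstruction and never claims numerical equality with the original
scanner's scores:

* **Scoring.** A window's score is its summed log2-odds against the
  background base frequencies, min–max normalised per matrix so that 1 is
  the best and 0 the worst attainable window — the classical "matrix
  similarity" idea. Matrices are regularised with a pseudocount (default
  0.01); `N` scores as background (log-odds 0); both strands are scanned,
  with minus-strand matches reported at the leftmost plus-strand base.
  The default threshold 0.85 is the conventional similarity cut-off.
* **Frameworks.** A module is an ordered motif pair with a start-to-start
  spacing window (default 5–200 bp; the "tandem" preset is same strand,
  fixed order, 5–50 bp) and a strand rule. Identical-span pairs are
  deduplicated and a physical site never pairs with itself in a
  same-motif model. `match_module()` is checked against an independent
  brute-force pair enumeration in the tests.
* **Discovery ranking.** The original framework-mining score is
  unpublished. `discover_frameworks()` ranks motif pairs by a
  chance-probability score: given per-motif background match
  probabilities (computed exactly, by dynamic programming over the
  discretised score distribution, in `pwm_match_prob()`), the expected
  number of chance site pairs inside the spacing window is
  Poisson-approximated, and the reported score is the binomial tail
  probability of the observed number of supporting promoters. This is
  *analogous* to, not identical with, the original tool's score; printed
  framework scores are therefore never used as reference values.
* **Enrichment.** The appearance ratio is total module matches divided by
  promoter-sequence count (it may exceed 1). For a framework, the four
  per-list ratios are summarised as mean ± sample SD (n − 1) and compared
  against the genome-wide background ratio — treated as a fixed constant
  — with a two-sided one-sample t-test on 3 degrees of freedom. The
  published table states only that ratios were "statistically compared";
  the one-sample t is the simplest test consistent with that description,
  and it reproduces the published significance for three of the four
  frameworks (< 0.0001, 0.0009, 0.0104) from the printed integer counts
  alone. The fourth row prints 0.0706 where this test yields 0.0761; the
  discrepancy is documented here and that value is not asserted anywhere.
  No correction across the twenty candidate frameworks is applied,
  matching the original analysis.

Because real promoter retrieval coordinates and matrices are unavailable,
the packaged motif file is an IRF-like *stand-in* (an AANTGAAA-style
core), and all matrix-dependent numbers in tests come from synthetic
promoters; published module counts enter only as a packaged count table.

## The synthetic-data generators

`simulate_expression()` draws per-probe log2 baselines from
N(7, 1.5²) — linear medians near 128, spanning dim to bright probes —
adds the planted per-condition log2 effect in treated samples, and
per-array N(0, 0.25²) noise; signals are `2^(.)`. Calls are Present when
the linear signal clears 50 (the same constant as the intensity floor),
with a symmetric 2% flip rate; the published data give no call model, and
this minimal one suffices to exercise the call filter. One root seed is
expanded into named substreams (`substream_seed()`) so stages are
reproducible independently; all seeds are recorded in the output
metadata.

Planted signature probes draw their baseline from the same normal
*truncated above* `log2(50) + 1`. A signature gene silenced below the
detection floor in every group would be removed by the intensity rule
regardless of any planted effect, so without the truncation a "recovery"
figure measures the floor rather than the test chain. With it, planted
recovery at log2 effect 2 and noise SD 0.25 is complete in both
directions with no direction errors.

`simulate_promoters()` emits i.i.d. background sequence at a given GC
content (default 0.5, length 601 bp — a −500..+100 TSS window) and plants
at most one framework instance per selected sequence at a uniform legal
offset, recording offsets, spacing and strand as ground truth. Planted
sites are matrix consensus by default (matches by construction at any
sensible threshold); per-position sampling from the matrix is available.

What the generators deliberately do **not** emulate: probe-level PM/MM
structure, array normalisation artefacts, correlated noise between genes,
dinucleotide or repeat structure in promoters, and the unknown true
promoter-per-gene mapping (the data model allows several promoters per
gene, but synthetic sets use one). Passing tests therefore demonstrate
the correctness and calibration of the *chain*, not the recoverability of
the published gene lists from the deposited raw arrays, which would
require the external array data and is out of scope.

## Validation arithmetic

`ddct_fold_change()` implements relative quantification with a designated
reference gene (GAPDH for the SYBR chemistry, Irf1 for the TaqMan assays;
the reference used is recorded on the result): fold change =
`efficiency^-ΔΔCt` with group Ct means, default efficiency 2. "Peaked
earlier" is operationalised by `time_to_peak()` as the argmax over
sampled time points, ties to the earliest, with a right-censoring flag
when the maximum sits at the last time point — the sampling grid, not a
fitted curve, defines the resolution. Group comparisons use Student's
pooled t (`compare_groups()`), with `fisher_lsd()` providing the
protected pairwise procedure after one-way ANOVA for more than two
groups; p < 0.05 is the conventional significance level in that stage.

## Problem sizes and numerical choices

The test suite and the acceptance script use sizes chosen to make the
Monte-Carlo answers stable at interactive run times: 10,000 probes for the
null-calibration run (about 8,200 eligible probes after filtering), 40
planted genes × 2 conditions for recovery, 100–150 bp × 100 sequences for
the brute-force scanning oracles, and 30 promoters × 11 motifs for
discovery ranking. Score discretisation in `pwm_match_prob()` uses 4,000
bins, giving tail probabilities accurate to well below the ranking
differences that matter. All tolerances asserted against published
numbers are at the precision those numbers were printed with (3 decimals
for ratios; integer counts elsewhere).

## Worked fixture example

```{r fixture}
lists <- jtx_gene_lists()
vapply(lists, nrow, 0L)
nrow(intersect_lists(lists[["GFLI-down"]], lists[["SPFLI-up"]]))
shared_genes(lists, min_lists = 3)
enrichment_table(jtx_module_counts())
```

## Known limitations

* The published gene lists themselves cannot be recomputed here — that
  requires the deposited raw arrays; the packaged tables are inputs, not
  outputs, of this package.
* The framework-discovery score is a reconstruction; only its *ranking*
  behaviour is tested, on synthetic truth.
* Welch-based screening at n = 3 rejects below its nominal level (see
  above); users wanting exact nominal calibration at this sample size
  should be aware this is a property of the method, not of the
  implementation.
* The one-sample enrichment test treats the background ratio as a known
  constant; with 51,460 background promoters its sampling error is
  negligible relative to the four-list SD, but a two-proportion view
  would differ for small backgrounds.
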