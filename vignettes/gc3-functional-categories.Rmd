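---
title: "GC3 composition of KOG functional categories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GC3 composition of KOG functional categories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kogGC3)
```

## The question and the quantities

Synonymous codon positions are where base composition can drift with the
least protein-level consequence, so the GC fraction at third codon
positions (GC3) is a sensitive readout of the compositional forces acting
on a genome — isochore structure, GC-biased gene conversion, thermal and
metabolic hypotheses all make statements about it. This package asks a
functional question of GC3: when protein-coding genes are grouped by KOG
functional class (25 single-letter classes, rolled up into the three broad
categories conventionally coloured **Blue** — information storage and
processing, **Black** — cellular processes and signaling, and **Red** —
metabolism), is composition distributed evenly across function, or do
metabolic genes sit systematically at the GC-rich end?

The pipeline computes, per genome:

* per-gene GC and GC3 (`gene_records()`), with GC defined as
  (G+C)/(A+C+G+T) and GC3 the same ratio over third codon positions only;
* the Blue/Black/Red hierarchy test (`category_hierarchy_test()`);
* ternary (de Finetti) occupancy of the categories over a Low/Medium/High
  split of the class-mean GC3 range, and a permutation test of the Red
  category's confinement to the High corner (`definetti_permutation_test()`);
* butterfly tables of per-class deviation from the genome mean
  (`butterfly_analysis()`, `butterfly_recurrence()`);
* GC3 increments over best-reciprocal-hit ortholog pairs between two
  genomes (`delta_gc3()`);
* association of classes and categories with the four human chromosomal
  band types L1+, L1−, H3−, H3+ (`band_frequencies()`,
  `category_band_chisq()`, `class_proportion_ztest()`,
  `group_band_comparison()`).

## Composition rules

Ambiguity code `N` is excluded from both numerator and denominator of GC
and GC3; this avoids biasing composition estimates by ambiguous calls.
Terminal stop codons are counted like any codon (the effect is at most
1/n_codons and there is no principled reason to special-case them in a
composition, as opposed to codon-usage, analysis). A sequence with no
countable base signals a classed condition (`kogGC3_undefined_composition`)
rather than silently returning 0. CDS whose length is not a multiple of 3
are an error under the default `strict` policy; `truncate` drops the
trailing partial codon with a warning, which matches how public CDS
annotations occasionally arrive. Tests are run under `strict` so synthetic
inputs fail loudly.

## The KOG catalog and filters

The 25-class catalog ships hard-coded (`kog_classes()`) together with
reference human per-class gene counts, mean GC3 and sd; the KOG scheme is
frozen upstream, so this is reference data, not configuration. The dataset
filters mirror the standard protocol for this analysis: (i) genes mapped
to more than one class are removed; (ii) the poorly characterized classes
R and S are removed (≈19% of the reference dataset); (iii) classes left
with fewer than 100 genes (M, N, Y in the reference data) are removed.
The size rule is strictly less-than — a class of exactly `min_class_size`
genes survives — and is applied to the counts that remain after rules
(i)–(ii). The filter report exposes the R+S fraction on both the full and
the post-multi-class denominator, since the published "about 19%" does not
say which was used.

A note on the shipped reference counts: the per-class counts sum to
16 108, and 16 108 − 3 060 (R+S) − 106 (M+N+Y) = 12 942, which is exactly
the human KOG dataset size the reference species table reports. The
associated grand total is elsewhere printed as 16 118; the class counts
are taken as authoritative because they reconcile exactly with the
retained-dataset size.

## Orthology and label transfer

Classes are defined on human genes; other genomes acquire labels through
orthology. Operational orthologs are best reciprocal hits (BRH): (a, b)
is a pair iff b is a's unique best hit forward, a is b's unique best hit
in reverse, and both e-values are below `1e-5` (strict inequality). Ties
for best — identical score and e-value on distinct subjects — drop the
query from pairing, the conservative reading of "best". The output is a
partial matching (no id appears twice) and is exactly transposed when the
two directions are swapped.

The builtin scorer exists so the package is testable without external
executables: a shared-3-mer count prefilter picks `n_candidates = 5`
subjects per query, which are then aligned with Smith–Waterman (BLOSUM62,
gap open 11, extend 1, as in common protein search defaults). The
attached pseudo-evalue is Karlin–Altschul-shaped,
`E = K · m · n_db · exp(−λS)` with gapped BLOSUM62 constants λ = 0.267,
K = 0.041. It is a documented monotone transform of the score used for
thresholding — not a calibrated significance value; with ~100-residue
queries it keeps unrelated random-sequence hits (scores ≈ 30–45) far
above the `1e-5` cut and planted orthologs at a few percent divergence
far below it. Real search output in the standard 12-column tabular format
(`read_tabular_hits()`) can be substituted at the same interface, which is
what a production run against public proteomes would do.

## Statistics

**Hierarchy test.** Pairwise two-sided Mann–Whitney comparisons
(Red–Black, Red–Blue, Black–Blue) on gene-level GC3, direction read from
the sample means. `mann_whitney()` uses the exact null distribution when
`min(n, m) ≤ 8` and there are no ties, otherwise the normal approximation
with tie and continuity corrections (the implementation delegates to
`stats::wilcox.test` under exactly that branch rule; tests verify the
exact branch against exhaustive enumeration). The verdict is `PATTERN`
when all three p-values are below α and the means are ordered
Blue < Black < Red; `PARTIAL` when Red significantly exceeds both others
but Black–Blue is not significant (the pattern seen in marsupial and
monotreme genomes); `NONE` otherwise. No multiple-testing correction is
applied across the three tests — the trio is reported jointly and the
butterfly analysis is where the family-wise correction belongs — and the
output says so.

**Butterfly.** Each class's gene-level GC3 is compared with the genome
mean by a two-sided one-sample t-test, treating the genome mean as a
constant. The one-sample design (rather than class vs complement) is the
natural reading of comparing a class "with the genome", whose mean is
computed over all available CDS — including the class itself — and is
essentially noise-free relative to a single class. Bonferroni multiplies
by the number of retained classes (20 under the reference filters),
capped at 1. Zero-variance classes report their deviation sign but no
p-value. When the full CDS set is unavailable the genome mean falls back
to the KOG subset with a warning.

**Ternary confinement.** Per genome, the range of class-mean GC3 is split
into three equal-width intervals (Low/Medium/High). Class means — not
gene-level values — define the range: classes are the plotted objects,
and a gene-level range would compress every class into the middle
interval. Interval bounds are half-open with the boundary belonging to
the upper interval, the last interval closed. Each category's ternary
point is the fraction of its classes per interval. The confinement
statistic is `S = mean over genomes of (p_high − p_low)` of the Red
point: +1 when Red is fully confined to High, 0 under symmetry, negative
toward Low. It is the simplest scalar monotone in "confined to the
GC-rich corner"; an alternative (mean Euclidean distance of the Red point
from the Low vertex) is available via `statistic = "dist_low"`. The
permutation test shuffles category labels over classes independently
within each genome, preserving category sizes and each genome's multiset
of interval assignments, and uses the add-one estimator
`p = (1 + #{S_perm ≥ S_obs}) / (n_perm + 1)`, which is valid under finite
permutation counts and never returns 0. With 200 permutations the
rejection rule at α = 0.05 is necessarily conservative (the add-one
estimator's attainable p-values top out at 10/201 below α), which the
null-calibration run reflects.

**Bands.** The four band types are ordered L1+ < L1− < H3− < H3+ by
increasing GC; the map from genes to bands is an input, not something the
package derives. The category association test is Pearson's χ² without
continuity correction on the 3 × 2 table against H3− and H3+ (df = 2),
with a warning when any expected count falls below 5. Class-level
comparisons use the pooled two-proportion one-sided Z-test on the class's
share of each band's genes (band totals as denominators); the
class-internal profile over bands is also emitted for plotting, since
both normalizations are in circulation. The positive/negative group
comparison partitions classes by butterfly sign and tests the positive
group's share in H3+ against L1+ (one-tailed).

## The synthetic generator

`generate_genome()` draws per-gene GC3 targets Normal(μ, σ) per class,
truncated to [0.02, 0.98] (untruncated tails would demand all-GC or
all-AT third positions, which the constructive encoder cannot always
satisfy), then realizes each target *exactly*:
`sequence_from_gc3()` places `round(target · n_codons)` G/C third
positions and draws the first two codon positions from the 14
dinucleotides that cannot begin a stop codon, so every codon is sense by
construction. Realizing composition exactly keeps the composition tests
sharp; all stochasticity lives in the Normal draw. Default CDS length is
120 codons — short for a real gene but long enough that GC3 granularity
(1/120) is far below the planted effects, and cheap to align.

`mutate_orthologs()` applies per-base substitutions at a given rate
(default 2%, a within-mammal-like protein divergence once translated),
codon-aware so no stop codon is ever created, and can re-balance third
positions to shift a copy's GC3 by a planted per-category increment —
the ground truth for the ΔGC3 analysis. `generate_band_map()` draws each
gene's band from a categorical whose log-odds toward GC-richer bands rise
linearly with the gene's GC3 (band scores −0.5, −1/6, 1/6, 0.5; slope 0 is
uniform; the default slope 6 gives a clear but noisy gradient, resembling
the monotone band–GC relation seen in real data without being
deterministic).

The `table1_spec()` configuration reproduces the shipped human reference
structure: the 20 retained classes with their published sizes, means
(0.517–0.646) and sds (0.117–0.172). A `scale` multiplier shrinks class
sizes for fast studies; the pipeline default is `scale = 0.1` (~1 290
genes), which keeps a full end-to-end run near ten seconds while leaving
every stage's behaviour qualitatively intact.

What the generator does *not* emulate: realistic codon usage or amino
acid composition, indels, paralogous families, gene length variation,
genuine isochore spatial structure (bands are drawn gene-wise,
conditionally independent given GC3), and correlated noise between
classes. Passing tests on this synthetic world therefore demonstrate that
the statistical machinery recovers planted compositional structure — not
that any particular real genome exhibits it. Conversely, the headline
real-data observations (e.g. human genome-wide GC3 ≈ 0.585, the
significantly-high class set {K, T, Z, G, E, P}, band-association
p-values) require full genome downloads and are treated as documented
expectations in the reference tables, not as test gates.

## Problem sizes and seeds

The test suite and the acceptance script run, by design, at these sizes:
hierarchy recovery at the planted study conditions (three categories,
1 200 genes each, means 0.56/0.58/0.60, sd 0.15, 100 seeded runs); null
calibration of the permutation test over 500 replicates of 200
permutations on 14 genomes × 20 classes; BRH recovery with 500 planted
pairs plus 100 decoys over 10 seeds; oracle equivalence on 1 000 random
CDS and all Mann–Whitney sample sizes up to 7. Every stochastic step
takes an explicit integer seed; generators save and restore the caller's
RNG state, so library code never perturbs a user's session RNG.

One power note, because it is easy to misread: at the planted hierarchy
conditions above, the two adjacent category gaps are 0.02 with sd 0.15 at
n = 1 200 per group, giving each adjacent Mann–Whitney comparison roughly
z ≈ 3.2 and ~89% power two-sided at α = 0.05. The all-three-significant
`PATTERN` verdict therefore lands near 80% of runs, not ≥95%; reaching
≥95% joint recovery at these effect sizes requires roughly double the
per-category sample. The package reports the honest recovery rate rather
than adjusting the planted conditions to flatter it.

## Known limitations

* The builtin aligner's k-mer prefilter can, in principle, miss a true
  best hit whose 3-mer overlap is outside the top candidates; at the
  divergences this package simulates (≤5%) this was never observed, and
  real analyses should import real search output anyway.
* The pseudo-evalue is not calibrated against BLAST; only its monotone
  ordering and rough scale are used.
* The confinement statistic is one reasonable choice among several; the
  permutation machinery is statistic-agnostic and exposes the
  alternative.
* Band maps are inputs; nothing here derives band types from coordinates
  or sequence.
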