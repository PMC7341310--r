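---
title: "Methods: trio transcriptome analysis of heterosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio transcriptome analysis of heterosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triohet)
```

# The design

A trio experiment measures one hybrid (for instance a mule or hinny) together
with samples representing its paternal and maternal parent lines, in one or
more tissues, with biological replicates per group. The scientific question
is how the hybrid's transcriptome relates to the two parental ones: for each
gene (expression level) and each alternative-splicing event (percent
spliced-in, PSI), is the hybrid at the mid-parent value (additive
inheritance), at one parent (high- or low-parent dominance), beyond both
parents (over-/under-dominance), or indistinguishable from both (conserved)?
The distribution of genes over these gene-action modes is the standard
summary in heterosis studies.

`triohet` implements this pipeline end to end on tabular inputs: a gene ×
sample count matrix, a sample sheet assigning each sample a species role
(`hybrid`, `paternal_parent`, `maternal_parent`) and tissue, a splice-event
table with per-sample inclusion/skipping junction counts, long-read
alignments as BED12, and gene sets as GMT. All genomic intervals are 0-based
half-open, matching BED, both on disk and in memory.

# Differential expression

`test_de()` is a deliberately minimal two-group negative-binomial Wald test:

* **Normalization.** Median-of-ratios size factors (`size_factors()`): each
  sample's factor is the median over genes of its count divided by the
  gene's geometric mean across samples, rescaled to geometric mean 1. This
  assumes most genes are not differential between the samples being
  normalized; compositions in which the majority of genes shift in one
  direction bias every downstream contrast. The `pseudo_reference` flag
  switches the per-gene reference to the geometric mean over positive
  entries only, for sparse matrices with no everywhere-positive gene.
* **Dispersion.** Per-gene method-of-moments on pooled within-group
  residuals of the normalized counts, under the parameterization
  `Var = mu + alpha * mu^2`. With typical replicate numbers (2-4 per group)
  this estimate is extremely noisy, and noise in the downward direction
  directly inflates the Wald statistic. The per-gene estimate is therefore
  floored at the pooled median of the positive per-gene estimates (which
  also serves as the fallback when the moment estimate is non-positive).
  No mean-dispersion trend is fitted: this is a desk-scale tool, and the
  flooring alone brings the null rejection rate at nominal 0.05 into the
  0.03-0.08 range that the test suite checks by simulation.
* **Test.** The Wald statistic is the log2 ratio of fitted group means over
  its delta-method standard error, computed on the normalized scale
  (`Var(n) = mu + alpha * mu^2`), so jointly rescaling one sample's counts
  and its size factor leaves every result unchanged — an invariance the
  suite asserts exactly. Two-sided normal p-values are BH-adjusted across
  all genes within the comparison. Group means of exactly zero are floored
  at half a normalized count so degenerate genes keep finite statistics;
  genes all-zero in both groups report `log2fc = 0`, `p = 1`.
* **Reporting.** The displayed `log2fc` uses a pseudocount of 0.5; the test
  statistic does not. DEG calling (`call_degs()`) is strict on both axes:
  `padj < 0.05` and `|log2fc| > 1`, mirroring the conventional printed rule.

# Differential splicing

PSI is estimated as `(I/lI) / (I/lI + S/lS)`: inclusion and skipping
junction counts debiased by the effective lengths of the two isoform forms.
Samples with `I + S` below `min_total` (default 10 junction reads) are
treated as missing.

`test_das()` models each replicate's `(I, S)` as binomial with a shared
group-level success probability `p(psi) = psi*lI / (psi*lI + (1-psi)*lS)`
and compares one common probability (null) against free group probabilities
by a likelihood-ratio test on 1 df. Because within an event both groups
share `lI` and `lS`, the likelihood depends on `psi` only through `p`, which
is a monotone bijection of `psi`; the MLE is therefore available in closed
form (the pooled `I/(I+S)`, inverted through the length weighting) and no
numeric search is needed — with equal effective lengths the group estimate
reduces to the pooled inclusion fraction, which the suite checks explicitly.
This is a simplification of hierarchical replicate-aware splicing models:
replicates enter a joint likelihood without a per-replicate random effect,
so between-replicate overdispersion in PSI is not modelled. On
binomially-generated data the null p-values are uniform (checked by a KS
test at 2000 events); on real data with extra replicate variance the test
will be anti-conservative, which is the main known limitation.

Calling (`call_das()`) follows the rigorous convention exactly as printed:
`|delta psi| > 0.10` strictly, `FDR <= 0.05` inclusively. Gene-level counts
are the unique genes with at least one called event.

# Gene-action classification

Every gene/event receives four contrasts: hybrid vs paternal (`hp`), hybrid
vs maternal (`hm`), paternal vs maternal (`pm`), and hybrid vs the
arithmetic mid-parent `(P + M)/2` (`mid`). For expression the mid-parent
contrast is a Wald test of the hybrid mean against the average of the two
parental means (variance of the average by the delta method from the same
NB fit); for PSI it is a 1-df LRT of the hybrid samples' likelihood at
their own MLE versus at the fixed mid-parent PSI. Fixing the null at the
parental point estimate ignores parental uncertainty and is therefore
slightly anti-conservative; with two or more replicates per parent at the
coverages simulated here the effect is small (the planted-additive recovery
test bounds it).

Relations are derived purely from significance: a contrast is `equal` when
its BH-adjusted p is at least `alpha` (default 0.05), else `greater`/`less`
by the sign of the estimate. The classifier applies a fixed precedence:

1. all three pairwise relations equal → `conserved`
2. H > P and H > M → `over_dominance`
3. H < P and H < M → `under_dominance`
4. hybrid equal to the strictly higher parent → `high_parent_dominance`
5. hybrid equal to the strictly lower parent → `low_parent_dominance`
6. parents differ and hybrid equals the mid-parent → `additive`
7. otherwise → `other_non_additive`

The precedence resolves overlaps that the verbal definitions leave open
(e.g. `H = P > M` satisfies a dominance reading and nothing else only if
dominance is checked before additivity); the enumeration test verifies the
implementation against an independently written rule table over all 81
relation combinations, plus exact parent-relabelling symmetry. The
`other_non_additive` residual class holds genes that are significantly
different from the mid-parent while strictly between the parents, matching
the residual "non-additive" column of conventional mode tables.

Two statistical consequences are worth knowing. First, "equal" is absence
of evidence: low-powered contrasts inflate the dominance and conserved
classes. In particular, planted-additive genes whose hybrid-vs-parent
difference (half the parental gap) goes undetected are absorbed into the
dominance classes, so additive recovery is intrinsically power-limited —
the suite asserts ≥90% recovery only for the four directional modes.
Second, because relations use BH-adjusted p-values, the realized
per-contrast threshold adapts to the non-null fraction: with dense planted
alternatives the conserved false-call rate rises above the naive
per-contrast `alpha`. Under a null-majority composition it stays near
`alpha` per contrast, which is the setting in which the suite bounds it.

`summarize_modes()` excludes conserved features from the denominator
(published tables classify only the differential features) and reports
percentages rounded half away from zero to one decimal; `mode_table()`
lays out per-(tissue, hybrid) rows in the conventional column order with
the non-additive, over+under and high+low aggregates.

# Long-read verification

A called event claims two expressed isoforms. `validate_long_reads()`
checks both against long-read alignments: a gene is *covered* when any
read on the same chromosome and strand overlaps the span of one of its
called events, and *verified* (default `both_isoforms` mode) when some
called event has both its inclusion and exclusion intron chains each
supported by at least one read; `any_isoform` is available for sensitivity
analysis and is never smaller. A read supports a chain when its intron
junctions restricted to the event span equal the chain's junctions with
every boundary within ±10 bases (long reads carry splice-site alignment
noise; the tolerance is configurable). A junction-free chain — the
retained form of an intron-retention event — is supported by a read block
that covers the whole span without any junction inside it. The headline
percentage is `round(100 * verified / covered)` at gene level, reported as
undefined (not zero) when nothing is covered.

# Enrichment

`enrich_sets()` is a local over-representation test: upper-tail
hypergeometric p-values (identical to one-sided Fisher's exact, asserted to
1e-12 in the suite), BH-adjusted across sets, with the count-matrix genes
as the default universe. Query genes and set members outside the universe
are dropped with a message; sets smaller than 3 after filtering are
skipped. Cross-species ortholog mapping, database snapshots and web
annotation services are deliberately out of scope — the caller supplies
the GMT.

# Correlation clustering

`correlate_samples()` computes Pearson correlations of
`log2(normalized + 1)` expression (or raw PSI with pairwise-complete
handling of missing values) and clusters samples by average linkage on
`1 - r`. The expression transform and linkage are package choices — the
conventional figures in this literature rarely state either. `top_split()`
exposes the two-cluster cut, used to check the expected
tissue-before-species structure.

# The synthetic-data generator

`trio_sim_config()` fixes the study conditions; the defaults are one
muscle tissue, 3 replicates per role, NB dispersion `alpha = 0.1`
(a typical bulk RNA-seq value), log-normal baseline means
(`meanlog = 5, sdlog = 1.5`, i.e. a median around 150 counts), library-size
multipliers log-uniform in [0.7, 1.4], planted effect size 2 log2 units,
baseline PSI uniform in [0.2, 0.8], planted PSI difference 0.3, Poisson
junction coverage 200, Poisson long-read depth 5 with 10% of events
uncovered. Group means encode the planted mode exactly: additive hybrids
at the arithmetic mid-parent of parents separated by the effect size,
dominant hybrids at one parent, over-/under-dominant hybrids beyond the
extreme parent by the same margin. Planted PSI values are drawn inside
per-mode feasible windows so every group PSI stays within [0.02, 0.98];
conserved events may use the full range including the boundaries. Long
reads copy an event's inclusion or exclusion chain with probability equal
to the hybrid's true PSI. One master seed drives everything, with
documented per-stage offsets (counts at `seed`, events at `seed + 1`,
long reads at `seed + 2`), so full datasets are bit-reproducible.

What the generator does *not* emulate: per-replicate PSI overdispersion,
mean-dispersion trends, outlier counts, alignment or sequence-level error,
isoform structures beyond two chains per event, and genes whose mode
differs between tissues (tissue effects scale all three groups jointly).
Passing the planted-recovery tests therefore demonstrates correctness of
the inference machinery under its own model assumptions, not performance
on real tissue data.

# Problem sizes and numerical choices

The simulation-based checks run at sizes chosen to make Monte-Carlo noise
small relative to the asserted margins: 2000 genes/events for the null
calibration checks, 1500 genes at coverage ~500 for mode recovery, 1000
events for splicing recovery, 20 replicate datasets of 300 genes × 2
tissues for the clustering structure, and 40 replicates per parent for the
dispersion-recovery check (the moment estimator needs that many degrees of
freedom for a tight per-gene interval). Percentages are rounded half away
from zero (banker's rounding would disagree with published tables at
exact .5 ties). The mid-parent PSI null is clamped to [1e-6, 1 - 1e-6] so
boundary estimates keep finite likelihoods; `0 * log(0)` terms in binomial
likelihood kernels are defined as 0.

# Limitations

No GLM covariates, no shrunken fold changes, no outlier refitting, no
paired designs, no parent-of-origin modelling (reciprocal-cross asymmetry
is reported by running each hybrid separately, not modelled jointly), and
no junction discovery — events are taken as given. The DE and DAS tests
are documented simplified equivalents of the field-standard tools, suited
to simulation-verified desk-scale analysis.
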