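---
title: "Methods: cis-positional lncRNA analysis with cislncDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-positional lncRNA analysis with cislncDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cislncDE)
```

# Scope and data model

cislncDE analyzes summarized log2 expression (features × samples) together
with a gene annotation split into protein-coding genes and lncRNA genes.
It does not touch raw arrays or reads: normalization and summarization are
upstream concerns. Internally all coordinates are 0-based half-open
(`length = end − start`, BED-compatible); GTF input (1-based closed) is
converted at the boundary, and a gene's *transcriptional unit* is the union
span of its annotated rows — TSS-most to TES-most coordinate, introns
included. Intronic placement therefore counts as intragenic, which is
deliberate: intronic sense lncRNAs are typically the largest intragenic
class in mammalian tissue, and an exonic-overlap rule would misplace them.

# Differential expression

Each stratum (age group) is an independent two-group contrast; there is no
longitudinal model. Per feature we compute group means of log2 intensity,
the pooled residual variance `s2` with `d_g = n1 + n2 − 2` degrees of
freedom, and a moderated t-statistic after shrinking `s2` toward a prior:

* Prior fit (`fit_ebayes_prior`): method of moments on `log s2`. With
  `e_g = log s2_g − digamma(d_g/2) + log(d_g/2)`, `mean(e)` locates `s0²`
  and the excess of `var(e)` over `trigamma(d_g/2)` determines `d0` through
  the inverse trigamma (Newton iterations, tolerance 1e-10). When the
  empirical excess is ≤ 0 — no detectable spread of true variances — we set
  `d0 = Inf` and use the pooled mean variance as `s0²`; this makes the
  degenerate all-equal-variances input return exactly that common value.
  Features with zero residual variance are excluded from the fit (with a
  warning count) but still tested under the squeezed variance.
* Test: `s̃² = (d0·s0² + d_g·s2)/(d0 + d_g)`, t on `d0 + d_g` df
  (the normal limit when `d0 = Inf`). With two groups this coincides with
  the per-contrast moderated ANOVA used by array software.

Fold change is the geometric-mean ratio `2^(mean log2 case − mean log2
control)`, not the ratio of anti-logged means. The two conventions differ
slightly under noise; the geometric one is consistent with the log-scale
model and is fixed throughout. Significance is the joint rule
`(FC > 2.0 or FC < 0.5) and q < 0.05` with BH q-values; both gates are
configurable (`fc_high`, `fc_low`, `fdr`).

# Positional classification

`classify_all` assigns exactly one class per lncRNA:

* overlap of ≥ 1 base with any gene's transcriptional unit → intragenic;
  sense if at least one overlapping gene shares the strand, else antisense.
  When both strands are overlapped, **sense wins** for the single label —
  one category per lncRNA keeps class counts a partition — but *all*
  overlapping genes remain in `partner_gene_ids` for pairing.
* no overlap → nearest gene by gap. The neighbor window is strict:
  `gap < 50 000` bases; exactly 50 kb is an orphan. The window is measured
  from transcriptional-unit boundaries, not TSSs (a flagged choice; TSS
  distance is a different, also defensible convention).
* nearest-gene ties (equal gap both sides) keep every tied gene as a
  partner rather than breaking the tie arbitrarily.

`relative_position` is computed in the partner gene's frame: a lincRNA
beyond the TES of a `+`-strand gene is *downstream*. The proximal flag
marks gaps strictly below 5 kb. Overlap and nearest queries run through
GenomicRanges interval trees; the test suite holds the results equal to a
brute-force all-pairs scan on hundreds of random annotations, so the index
is an optimization, never a semantic.

# Pairing and concordance

`build_pairs` joins significant lncRNAs to their significant partner genes
within a stratum, many-to-many: a host gene with three DE sense lncRNAs
contributes three pairs. The concordance table therefore reports both the
pair count `n` and the distinct-gene margin `n_genes`. Direction comes
from the sign of the DE table's log2 fold change; near-threshold features
that fail the joint rule contribute nothing. Cross-stratum totals are left
to the caller (`venn_membership` reports exactly which features recur), as
de-duplication across ages is a presentation choice, not a statistic.

# Chromosome-level density

`chrom_stats` reports, per named chromosome (unplaced scaffolds excluded),
the percentage of encoded features of a category that are DE, plus the
mean and *sample* (n−1) SD of those percentages across chromosomes — the
dispersion convention when a mean ± value summarizes chromosomes; a SEM
convention would need the same counts divided by √(#chromosomes).
Chromosomes encoding no feature of the category are flagged and excluded
from the summary.

# Over-representation

`ora` is a one-sided hypergeometric upper tail `P[X ≥ k]` per gene set,
BH-corrected across the collection. The universe defaults to all
protein-coding genes of the annotation and is configurable; background
choice is the single biggest lever in ORA and should be stated with any
result. The EASE-style penalized count (k − 1) used by some tools is not
applied; it is a documented variant that can be layered on the same
machinery.

# qPCR quantification

`ddct` averages technical triplicates per animal first — the animal is the
replication unit — then forms `ΔCt = Ct_gene − Ct_reference`,
`ΔΔCt = mean ΔCt_case − mean ΔCt_control`, and `FC = 2^−ΔΔCt`. Dispersion
is the SD of per-animal `2^−ΔΔCt` values in the case group (per-animal
rather than error-propagated — a flagged convention). The gate is a
one-way ANOVA on per-animal ΔCt, which for two groups equals the pooled
t-test (F = t², verified numerically in the tests). Undetected wells are
explicit NAs, never a sentinel Ct of 40; a gene undetected in a whole
group yields an NA fold change rather than a fabricated one. In the
noise-free limit the ANOVA is degenerate (zero residual); the p-value is
then defined as 0 when group means differ and 1 when they do not.
`ct_ratio_band` implements the cell-panel banding: mean Ct ratio to the
reference < 1.0 is high expression, > 1.8 low, between is intermediate,
undetected is no-expression.

# SAM cross-dataset statistic

`sam_test` computes `d = Δx̄ / (s + s0)` with `s` the pooled SE of the
mean difference. `s0 = "auto"` follows the original grid search: candidate
s0 values are the 5%-step percentiles of `s`; the chosen one minimizes the
coefficient of variation of windowed MADs of `d` across percentile windows
of `s`. q-values follow the original SAM FDR — for each observed |d| as a
threshold, the median permutation count of |d*| at or above it over the
observed call count — monotonized so q never decreases with |d|. Label
permutations are exhaustive when fewer exist than requested (with a
message), otherwise a seeded random sample; the seed makes q-values
reproducible. With `s0 = 0`, `d` is algebraically the ordinary pooled t
(held to 1e-12 in the tests). `harmonize` joins per-study DE tables by
stable gene id, resolves within-study duplicates by largest |log2 FC|
(warning), and calls per-feature agreement when ≥ 2 significant entries
share a direction.

# The synthetic-data generator

`simulation_config` defines a two-group (wt vs ob), age-stratified study.
Defaults: 4 chromosomes × 10 Mb, 60 coding genes, planted lncRNA counts
{sense 8, antisense 6, neighbor 20, orphan 6}, 4 replicates per group
(matching typical array designs of 3–4), planted |log2 FC| = 1.322
(linear 2.5, just above the 2.0 gate), background DE fraction 0.1, strata
16w/24w with a small 16w subset for a non-trivial Venn. The neighbor set
plants 13 proximal pairs (< 5 kb) of which 12 are direction-concordant,
12 downstream and 11 same-strand — the cis-regulatory fingerprint the
pair stage must reproduce — and 7 distal pairs at 6–49 kb. Genes are
placed by rejection sampling (cap 1000 retries per feature, with an error
advising a longer chromosome) at ≥ 120 kb edge separation, which
guarantees by construction that planted classes are unambiguous: no
accidental overlaps, and each neighbor's planted partner is its unique
nearest gene. All draws flow from one integer seed (sub-stages use fixed
offsets), so a config reproduces byte-identical fixtures.

The default residual SD is `log2_sigma = 0.1`, the low end of what
well-replicated expression arrays on homogeneous tissue achieve. The
default study is the *bookkeeping* demonstration — its planted structure
should be recovered exactly, isolating the deterministic machinery — so a
low noise floor is the appropriate default; detection behavior under
harder noise is probed separately by the calibration and power analyses,
which set σ = 0.25 explicitly. At σ = 0.25 a planted FC of 2.5 fails the
observed-FC gate (FC > 2) with probability ≈ 3.4% per feature — an
inherent property of gating on a noisy fold-change estimate, worth
remembering when interpreting joint-rule DE counts on real arrays.

What the generator does *not* emulate: probe-level effects, batch
structure, correlated features, heavy-tailed noise, or any true
cis-regulatory coupling beyond planted direction concordance. Passing the
planted-recovery tests demonstrates the pipeline's accounting is exact; it
does not certify detection performance on real tissue, which the
calibration/power simulations address only under the Gaussian model.

# Validation sizes and numerical choices

The test suite checks the interval index and classifier against
brute-force scans (50 random annotations of ≤ 500 features; 1000 random
queries), BH against step-up enumeration (all 720 orderings of six
p-values), the hypergeometric tail against mass summation for every
(N, K, n, k) with N ≤ 60, the moderated t against a scalar-formula oracle
(1e-10) and against limma's independent implementation of the same
moment estimator (1e-8), SAM at s0 = 0 against the pooled t (1e-12), and
the joint DE rule's calibration and power on 200 simulations of 2000
features at n = 4 vs 4. Prior recovery uses 10 000 variances drawn from
the scaled inverse-χ² hierarchy (d0 = 4, s0² = 0.05). These sizes keep the
whole suite in a few minutes on one CPU while leaving Monte-Carlo error
well below the asserted margins.

# Known limitations

* One label per lncRNA; a transcript overlapping gene A in sense and
  gene B in antisense is "sense" even though both pairings are reported.
* Boundary-gap distances ignore TSS orientation subtleties (bidirectional
  promoters are out of scope).
* ORA ignores gene length and expression-detectability bias.
* SAM uses full label permutations, not the balanced-only subset; with
  small n the difference is within permutation noise, and the exhaustive
  set is used whenever it is smaller than the request.
* Direction concordance is not co-expression: no across-sample correlation
  is computed, and no causal cis-regulation is implied.
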