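---
title: "Metabolic subtypes and association mining: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic subtypes and association mining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The procedure

metaboclust implements a two-stage analysis of tumor cohorts. In the first
stage, for every (tumor type, metabolic gene set) pair, samples are
partitioned into *metabolic subtypes* using only the expression of the
set's genes. In the second stage, every subtype partition is tested for
association against per-sample molecular and clinical features, with one
Bonferroni correction family per variable class pooled across all tumor
types.

The clustering stage for one pair is:

1. **Restriction.** The TPM-like expression matrix is restricted to the
   set's genes (exact symbol match after uppercasing); genes constant
   across samples are dropped. Fewer than two usable genes makes the pair
   *unusable* — a correlation between two samples cannot be defined on a
   single gene — and it is recorded as such, distinct from "no cluster
   structure".
2. **Gate.** A Duda–Hart test of the one-cluster null decides whether any
   cluster structure exists. The candidate 2-split is taken from PAM with
   `k = 2` on the Spearman distance (the same split family used
   downstream), and the test statistic is evaluated on rank-transformed
   coordinates (each gene replaced by its ranks across samples). Pairs
   with `p >= gate_alpha` (default 0.001) are *gated out* and produce no
   subtypes.
3. **Clustering.** Gated-in pairs are clustered with PAM on the distance
   `d = 1 - rho`, where `rho` is the Spearman rank correlation between the
   two samples' expression profiles over the set's genes. The number of
   clusters `k` is chosen in `2..k_max` (default 10) by maximizing the
   average silhouette width.

Clustering on a gene set rather than scoring its average expression
matters because metabolic pathways mix anabolic and catabolic arms: a
subtype activating a pathway typically shows *both* up- and downregulated
genes, a pattern invisible to a single set-level expression score. The
synthetic generator plants exactly this block structure.

## Statistical tests and correction

Each feature is dispatched by its variable class:

* **Continuous** (miRNA ranks, global methylation, SGOL copy-number
  scores, RPPA, continuous clinical): Mann–Whitney U for two subtypes —
  exact enumeration when both groups have at most 8 samples and no ties,
  otherwise normal approximation with tie correction — and Kruskal–Wallis
  for `k > 2`.
* **Categorical** (mutations, histology, categorical clinical): Fisher's
  exact test on 2x2 tables; Pearson chi-square without continuity
  correction on larger tables, after iteratively removing feature levels
  whose expected count falls below 5 (expectations recomputed after each
  removal, smallest expected minimum removed first; a table reduced to
  2x2 is routed back to Fisher for consistency). Fewer than two surviving
  levels invalidates the test.
* **Survival** (OS, RFS): log-rank across subtypes. The result is valid
  only when every subtype's expected event count is at least 5; with
  fewer expected events the statistic is unstable, so the result is
  flagged invalid regardless of its p-value.

miRNA matrices are rank-transformed with *random* resolution of ties
before testing. Bulk miRNA data contain many exact zeros; average ranks
would create massive tie groups whose discreteness distorts the rank
tests, whereas randomized ranks restore an exact null. The randomization
is driven by an explicit seed, so results are reproducible.

The Bonferroni family of a test is its variable class pooled over all
tumor types and gene sets: classes hold wildly different numbers of
variables (hundreds of miRNAs versus one overall-survival endpoint), and
a single overall correction would unduly penalize the small classes. The
family size `m` counts **valid** tests only — a test that produced no
p-value never entered the family. Because this choice changes thresholds
and is debatable, `count_invalid = TRUE` switches to counting all
attempted tests.

A *recurrent* association is a (gene set, variable class, feature) triple
significant in more than one tumor type, excluding tumor types that are
unions of narrower cohorts (default `LUNG, KIPAN, GBMLGG, COADREAD,
STES`, configurable): a union cohort would double-count its constituents.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `gate_alpha` | 0.001 | Duda–Hart gate level for cluster separation |
| `k_max` | 10 | largest number of clusters considered (clamped to n−1) |
| `alpha` | 0.05 | family-wise error level per variable class |
| SGOL thresholds | ±0.5 | dead zone on log2-ratio copy-number values |
| `min_expected` | 5 | expected-count floor for categorical levels |
| `min_expected_events` | 5 | expected-event floor for log-rank validity |
| `min_mutated_samples` | 3 | floor for testable point-mutation features |
| `max_levels` | 10 | free-text guard on categorical clinical columns |

Non-synonymous variant classifications default to the nine standard MAF
classes (`NONSYNONYMOUS_CLASSES`); the set is configurable because MAF
dialects differ.

## Design decisions in the open corners

Several components admit more than one reasonable operationalization;
the choices here are deliberate and fixed:

* **Duda–Hart variant.** The statistic is `H = Je(2)/Je(1)` — within-split
  over total sum of squares — with the normal approximation
  `z = (1 − 2/(πp) − H) · sqrt(np / (2(1 − 8/(π²p))))` and
  `p = 1 − Φ(z)`, computed in rank-transformed coordinates with the PAM
  2-split. Ranks are the more conservative input space compared to
  log-transformed values, and using the same split family as the
  downstream clustering makes the gate a statement about the structure
  that would actually be reported. Because the split is chosen by the
  data, the gate is anti-conservative relative to its nominal level; the
  calibration property asserted by the tests therefore fixes the split
  independently of the data, where the rejection rate must stay at or
  below the nominal 0.001.
* **Ranking direction.** Ranks are computed per gene across samples (not
  per sample across genes): clustering is per tumor type and per-gene
  ranking preserves the up/down block structure that defines subtypes.
* **Distance scale.** `d = 1 − rho` ranges over [0, 2]. PAM and
  silhouette rankings are invariant under affine rescalings such as
  `(1 − rho)/2`, so the choice is documented for reproducibility rather
  than substantive.
* **Determinism.** PAM is the classic BUILD + SWAP with every tie
  (initial medoid, added medoid, improving swap, nearest-medoid
  assignment) broken toward the lowest sample index, and cluster labels
  follow ascending medoid index. Repeated runs are byte-identical. PAM is
  a local search: on unstructured random distance matrices it reaches the
  exhaustive-search optimum in most but not all runs (the reference
  implementation in the `cluster` package behaves the same); on separated
  data agreement is exact, and the test suite asserts both.
* **Silhouette conventions.** Singleton clusters score 0, and the
  degenerate all-distances-zero case scores 0. Exact ties in the average
  silhouette width resolve toward smaller `k`.
* **SGOL per sample.** The GISTIC-like segment-gain-or-loss score sums
  thresholded values across samples, yielding one number per cohort —
  which cannot enter a per-sample association test. Here the thresholded
  value is kept per sample and averaged over the region's genes, making
  copy-number features testable sample-wise; the cohort-sum variant is
  available as `mode = "cohort_sum"` for comparison. Genes overlapping
  several segments get the length-weighted mean of segment means.
* **Name filter.** Metabolic gene sets are those whose name contains
  "metabol" but not "regul", case-insensitively. Collections differ in
  capitalization conventions, so the case-insensitive reading is the
  robust one.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` produce complete multi-omic cohorts
with known ground truth, so every pipeline stage is testable without
external downloads. The generator emulates the *statistical* structure
the pipeline consumes:

* log-normal TPM expression with planted gene-set-restricted subtype
  blocks (per cluster, an independent up/down pattern over the set's
  genes at a chosen log2 separation);
* zero-inflated log-normal miRNA counts;
* non-synonymous mutation calls with cluster-dependent probabilities;
* SEG-format segments on a toy genome (2 chromosomes × 10 Mb, 100 genes
  on a regular grid) with a planted amplified region;
* exponential survival with cluster-dependent hazards and exponential
  censoring tuned to a target censoring fraction;
* categorical histology with cluster-dependent level probabilities.

Cluster sizes are balanced by default (imbalance can be specified, which
exercises the minimum-expected-count rules). All outputs are pure
functions of (spec, seed).

What the generator does **not** emulate: realistic TCGA marginal
distributions, batch effects, tumor purity, copy-number-to-expression
coupling, or correlated gene-gene noise within a set. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's statistical
correctness — calibration, power against planted effects, recovery of
planted partitions — not that any particular biological claim transfers
to real data.

Presets: `demo` (moderate separation, every effect class on), `null`
(no structure, no effects; the global-null condition used for error-rate
checks) and `strong` (log2 separation 4, for parameter-recovery studies).
Log-normal expression with additive log2-scale shifts was chosen over
negative-binomial counts because the pipeline rank-transforms its input:
only monotone structure matters, and the log-normal keeps effect sizes in
closed form.

## Numerical and degenerate-input choices

* Zero-variance genes are dropped before distance computation; a sample
  with zero variance across the subset genes is an error naming the
  sample (its Spearman correlation is undefined).
* A gene constant across samples gets `p = 1` in the differential-gene
  ranking (Kruskal–Wallis is undefined there; a constant gene cannot
  discriminate subtypes).
* A feature constant across samples likewise gets `p = 1` rather than an
  error.
* Swap improvements smaller than 1e-12 are treated as ties to avoid
  floating-point cycling in PAM.
* NMI is clamped to [0, 1] against rounding; a partition with a single
  cluster has zero entropy and NMI is defined as 0.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on synthetic
cohorts sized for quick, stable statistics: cohorts of 40–300 samples,
gene sets of 12–30 genes, 10,000-replicate calibration loops for the
fixed-split Duda–Hart gate and the nominal-level checks, 100–200
replicate loops for recovery, family-wise error and power. These sizes
are the package's own choice of a demonstration scale; the pipeline
itself has no size-dependent switches beyond the documented clamping of
`k_max`.

## Limitations

* The analysis is correlative; associations motivate mechanistic
  hypotheses and nothing more.
* The Duda–Hart gate with a data-derived split is anti-conservative by
  construction; its gate level is a screening convention, not a
  calibrated error rate.
* Only PAM is implemented; other clustering strategies (hierarchical,
  consensus) may partition differently and are out of scope.
* Bonferroni is the only correction applied to the reported significance
  flags; with hundreds of thousands of tests it is deliberately strict,
  and features with modest effects in small classes will be missed.
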