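---
title: "Methods: EMD subtype discovery and scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMD subtype discovery and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdgc)
```

## The model

Gastric tumours show extensive crosstalk between histone marks (H3K4me1,
H3K4me3, H3K27ac) and the mRNA modification m6A. `emdgc` operationalizes
that crosstalk in three layers:

1. **Site-to-gene evidence.** Differential histone sites act on genes
   through promoters (transcription-activating marks concentrate around
   the TSS), while m6A acts on the transcript body (3'UTR/exons). The two
   evidence criteria encode exactly this: criterion 1 requires a
   promoter-located differential histone site whose direction matches the
   gene's differential expression within one cell line; criterion 2
   requires an m6A site in the gene together with a correlation pattern
   consistent with m6A-dependent regulation — positive with
   writers/readers, negative with the erasers ALKBH5 and FTO. Genes
   satisfying either criterion are EMRGs; their lncRNA subset (EMRLs) is
   the feature space for subtype discovery, since lncRNAs are themselves
   regulatory and strongly tissue-specific.

2. **Subtype discovery.** Patients are clustered on survival-associated
   EMRLs by consensus clustering: repeated k-means on random 80% sample
   subsets, with the consensus matrix entry (i, j) the fraction of
   co-draws in which i and j co-clustered. The subtype with the worst
   Kaplan–Meier survival is labelled EMD.

3. **Scoring.** The EMD score transfers the subtype to new cohorts as
   `log2(ssGSEA(set1) / ssGSEA(set2))`, where set1/set2 are EMD-up and
   EMD-down signatures selected from the DEGs between the EMD and
   best-survival clusters.

The proportional-hazards screen, the log-rank read-out and the exact 2x2
tests are delegated to `survival` and `stats`; the evidence rules, the
single-sample enrichment statistic, the consensus-clustering loop, the
signature selection and all generators are implemented in this package
and are each checked against independent brute-force oracles in the test
suite.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| promoter `window` | 3000 bp | promoter = TSS ± 3 kb; distance bins <1 kb, 1–2 kb, 2–3 kb |
| site thresholds | \|fc\| > 1, p < 0.05 | differential-site (DHMS/MMS) filter |
| DEG thresholds | \|log2FC\| > 1, p < 0.05 | differential-expression filter |
| CEG thresholds | \|ρ\| > 0.3, BH p < 0.05 | Spearman correlation with the 22 m6A regulators |
| Cox screen `alpha` | 0.01 | survival-associated EMRL selection (Wald p) |
| `k_range` | 2:7 | consensus clustering maxK = 7; k fixed to 4 for the GC analysis |
| `n_resamples`, `item_frac` | 1000, 0.8 | consensus resampling; tests/pipeline use 50–250 resamples, which is ample at n ≈ 100 samples |
| `gs_threshold`, `mm_threshold` | 0.4, 0.7 | gene-significance / module-membership gates of the signature selection |
| ssGSEA `alpha` | 0.25 | rank-weight exponent of the enrichment statistic |
| rescale `eps` | 0.01 | floor of the per-cohort min–max rescale of the two enrichment scores |

## Numerical conventions

* **Coordinates** are 0-based half-open everywhere internally; GTF input
  (1-based closed) is converted on read and back on write, so
  read → write → read is the identity.
* **Promoter bins** are assigned by the minimum per-base distance to the
  TSS over the site's overlap with the window, so a straddling site gets
  the nearest bin deterministically, and the three bins exactly partition
  the window. Region precedence outside the promoter is 3'UTR > CDS >
  exon > intron > distal; sites on absent chromosomes are distal, not
  errors.
* **"m6A site in the gene"** is read as overlap with the exon union
  (which contains CDS and 3'UTR) or the promoter window — the same
  regions in which m6A peaks are tallied.
* **CEG statistic.** The correlation screen uses Spearman's ρ with a
  t-approximation p-value and BH adjustment over all gene×regulator
  pairs. (The source protocol annotates the correlation threshold with a
  rank test whose statistic has no \|r\|; a correlation coefficient is
  the only self-consistent reading, and its own figures label the
  correlations Spearman.) The adjusted-p gate inside criterion 2 can be
  relaxed with `require_adj = FALSE`.
* **Differential expression** is a per-gene Welch unequal-variance t-test
  on log2-scale values with BH adjustment — the package consumes
  normalized matrices, not counts, so count-model fits are out of scope;
  the pass thresholds are preserved verbatim. Zero-variance genes with
  equal means get p = 1 by convention.
* **Co-mutation** uses the exact conditional (hypergeometric) two-sided
  test, unadjusted at p < 0.05 as the co-mutation definition (a BH mode
  is available); direction is co-occurrence when the joint count exceeds
  its independence expectation.
* **Cox fits** use the Breslow tie approximation; non-convergent or
  constant candidates are flagged/excluded rather than failing the
  screen.
* **k-means seeding** inside the consensus loop is greedy
  spread-maximizing (maximin) from the run's RNG stream, 10 restarts,
  best within-cluster inertia kept; features are z-scored per gene before
  clustering (cohorts are assumed comparable; batch correction is
  upstream). "Euclidean" is the k-means metric. PAC uses the standard
  (0.1, 0.9) window. Whether to cluster z-scored or raw expression is not
  dictated by the protocol; z-scoring is this package's documented choice.
* **Signature selection** replaces a full weighted co-expression network
  analysis with a transparent surrogate: passing DEGs are split by the
  sign of their correlation with the EMD indicator (GS); each sign
  group's first principal component (oriented towards its member genes)
  is the module eigengene, and MM is the correlation with it. The
  GS ≥ 0.4 / MM ≥ 0.7 gates are configurable; with both at their
  degenerate minimum the selection reduces to the sign partition. The
  procedure keeps the selection semantics — trait-correlated,
  module-coherent genes — while being fully specified and testable.
* **EMD score.** Single-sample enrichment scores can be negative, which
  would make the log-ratio undefined; both score vectors are min–max
  rescaled into (0.01, 1] per cohort before the ratio (a global mode
  exists for single-sample cohorts). Ties at the cohort median go to the
  `low` group; Q1 uses the type-7 quantile, with scores equal to Q1 in
  the low group. ssGSEA ties in expression are broken by gene identifier.
* **Determinism.** Every generator and the consensus loop are pure
  functions of (configuration, seed) via an isolated RNG scope; the whole
  pipeline writes byte-identical outputs across repeated runs.

## What the synthetic data emulates — and what it does not

`simulate_config()` defines one coherent study: ~400 genes (the 43
regulators, filler protein-coding genes, 25% lncRNAs) tiled on a toy
chromosome with 20 kb spacing (promoters can never collide); four planted
patient clusters of equal size, the last (EMD-like) with +effect on the
set1 genes and FTO and −effect on the set2 genes and HDAC1; per-cluster
lncRNA marker blocks (12 genes each) that carry planted m6A sites and
share noise with a driving m6A writer/reader at correlation 0.8, so they
are discovered as EMRLs; histone sites with direction-matched cell-line
DEGs on a subset of signature genes, plus two deliberately discordant
decoys; distal background sites that never pass the filters; exponential
survival with log-hazard proportional to the standardized planted score
(baseline median OS 730 days, uniform censoring on (30, 3650) days,
observed times ≤ 30 days resampled, mirroring the usual 30-day exclusion);
responder probability a decreasing logistic of the score; and regulator
mutations at rate 0.12 with two planted co-mutation pairs (odds ratios 10
and 8). Defaults use effect size 2 and noise SD 1; the recovery
benchmarks in the tests use the well-separated regime (effect 3, noise
0.5, n = 120) and n = 500/200 for parameter-recovery checks, sizes chosen
so every property is decidable in seconds to a few minutes.

The generator does **not** emulate: read-level data or peak shapes,
batch effects between cohorts, copy-number or purity structure,
non-proportional hazards, within-cluster continuous variation of the
EMD phenotype, or realistic lncRNA/PCG expression distributions
(log-normal-ish baselines with homoscedastic Gaussian noise are used).
Two consequences are worth knowing. First, survival is driven by the
planted cluster level, so the Cox screen keeps mainly the markers of the
extreme clusters; the pipeline's four-cluster agreement on screened EMRLs
is therefore lower than clustering on the full EMRL set, while the EMD
subtype itself — the object of interest — is recovered exactly. Second,
the Q1 response contrast is diluted relative to a real cohort, because
the score cannot rank patients within the non-EMD clusters. Passing
tests on this benchmark demonstrates algorithmic correctness and
calibration, not clinical performance on real cohorts.

## Known limitations

* Headline counts from the original cohorts (e.g. thousands of EMRGs, 370
  EMRLs, 34 screened EMRLs, the 147/64-gene signature, AUC 0.96) depend on
  controlled-access data and full-scale ChIP/MeRIP processing and are not
  reproducible here; the package reproduces the *logic* that produced
  them and verifies it on planted ground truth.
* All inputs must be on a single assembly; no liftover is attempted.
* The CEG screen's t-approximation of Spearman p-values is asymptotic;
  at very small n (< 10 samples the functions refuse anyway) an exact
  permutation p would differ.
* Consensus clustering assumes the feature matrix is informative; with
  fewer than ~3 samples per candidate cluster the resampling degenerates
  and the functions error out rather than guessing.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the generator at n = 120
(subtype recovery, scoring, response), n = 500 (survival linkage,
hazard-coefficient recovery, null calibration of the Cox screen across
500 genes), and n = 200 (correlation recovery); oracle-equivalence checks
use 100–200 random fixtures each. A full run of the suite takes about a
minute on one core.
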