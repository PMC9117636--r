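# emdgc — epigenetic-modification-dysregulated subtype discovery and scoring in gastric cancer

`emdgc` implements an integrative epigenomics workflow for gastric cancer
(GC) that links histone-modification ChIP-seq and m6A MeRIP-seq evidence to
patient transcriptomes. It is aimed at computational biologists who have
pre-called differential modification sites and normalized expression
cohorts, and who want a tested, deterministic implementation of:

1. **EMRG/EMRL discovery.** A gene is an *epigenetic-modification-related
   gene* (EMRG) if either
   - **criterion 1 (histone):** a differential histone site (H3K4me1,
     H3K4me3 or H3K27ac; |fold-change| > 1, p < 0.05) lies in the gene's
     promoter (TSS ± 3 kb) and the gene is differentially expressed
     (|log2FC| > 1, p < 0.05) *in the same direction in the same cell
     line*; or
   - **criterion 2 (m6A):** an m6A site lies in the gene and the gene's
     expression is Spearman-correlated with the m6A machinery
     (ρ > 0.3 with a writer/reader, or ρ < −0.3 with an eraser — ALKBH5 or
     FTO — at BH-adjusted p < 0.05).

   EMRGs with the lncRNA biotype are EMRLs. A packaged catalogue of the 43
   epigenetic regulators (21 histone, 22 m6A) drives the correlation
   screens.

2. **EMD subtype discovery.** EMRLs are screened by univariate Cox
   regression (p < 0.01) and patients are consensus-clustered (resampled
   k-means, Euclidean distance, maxK = 7, k fixed to 4 for the GC
   analysis). The cluster with the worst Kaplan–Meier survival is the
   *epigenetic-modification-dysregulated* (EMD) subtype.

3. **EMD score.** From the DEGs between the EMD and best-survival
   clusters, an up-signature (`set1`) and down-signature (`set2`) are
   selected by gene-significance and module-membership thresholds, and per
   patient

   ```
   EMD score = log2( ssGSEA(set1) / ssGSEA(set2) )
   ```

   with both single-sample enrichment scores min–max rescaled into
   (0.01, 1] per cohort so the ratio is always defined. High scores mark
   EMD-like, stroma-activated, immune-suppressed, ICI-resistant patients;
   the FTO/HDAC1 expression ratio is computed alongside as a two-gene
   proxy of the same phenotype.

4. **Read-outs.** Kaplan–Meier curves with log-rank tests for the
   cohort-median score split, ROC/AUC for subtype recognition, and the
   lower-quartile (Q1) split of ICI responder rates with an exact test.

Because the original cohorts are controlled-access, the package ships a
first-class synthetic-data module (`simulate_*`) that generates every
input — annotation GTF, site tables, expression matrix with four planted
patient clusters, survival, ICI response and mutation matrices — with
known ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(emdgc)
cfg <- simulate_config(seed = 1, effect_size = 3, noise_sd = 0.5)
res <- run_emd_pipeline(cfg, n_resamples = 200)
round(res$summary, 3)
#>             n_emrg             n_emrl         n_screened       ari_vs_truth
#>             58.000             48.000             24.000              0.658
#>            auc_emd          logrank_p  response_rate_low response_rate_high
#>              1.000              0.002              0.367              0.400
#>  response_fisher_p    ratio_score_rho
#>              0.831              0.582
```

Reading the numbers: the two criteria recovered 58 EMRGs, of which all 48
planted lncRNA markers are EMRLs; 24 EMRLs pass the Cox screen (survival
in the simulation is driven mainly by the extreme clusters, so mid-cluster
markers are filtered — hence the pipeline's four-cluster agreement with
the planted labels, `ari_vs_truth`, is 0.66 while clustering on the full
EMRL set recovers the planted clusters exactly; see the acceptance
script). The EMD subtype itself is found perfectly: the EMD score
recognizes the planted EMD cluster with AUC 1.0, its median split is
prognostic (log-rank p = 0.002), and it correlates with the FTO/HDAC1
ratio (Spearman ρ = 0.58). The Q1 response contrast is diluted here
because, in the generator, response depends on the planted cluster level
and the EMD score cannot rank patients within the non-EMD clusters.

```r
res$consensus
#> consensus_result: k in {2,3,4,5,6,7}, chosen k = 4
res$signature
#> emd_signature: 54 set1 (up), 26 set2 (down) genes
head(res$scores[, c("sample_id", "ssgsea1", "ssgsea2", "emd_score", "score_group")], 2)
#>   sample_id  ssgsea1  ssgsea2 emd_score score_group
#> 1      S001 23.63465 9.326161 -3.603248         low
#> 2      S002 31.65632 2.519640 -2.773572        high
```

All stages are exported individually (`read_gtf`, `read_site_table`,
`classify_site_region`, `differential_expression`,
`correlate_with_regulators`, `comutation_test`, `cox_screen`,
`emrg_criterion1/2`, `build_catalog`, `consensus_cluster`,
`label_emd_cluster`, `select_signature`, `ssgsea`, `emd_score`,
`fto_hdac1_ratio`, `km_logrank`, `score_auc`, `response_contrast`) so the
pipeline can be run on real site tables and cohorts file by file;
`write_simulation()` emits a complete plain-text fixture directory.

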