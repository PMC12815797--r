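# tregstrat

Integrative multi-omics subtype discovery for tumors with regulatory
T cell (Treg) driven immunosuppression, plus the preclinical efficacy
arithmetic used to evaluate Treg-directed combination therapy.

Tumors enriched in Tregs (FOXP3+, CCR8-high) suppress cytotoxic immunity
and resist checkpoint blockade. `tregstrat` implements an end-to-end,
fully testable pipeline for finding such a subtype from bulk multi-omics
data and for quantifying whether a CCR8-antagonist plus anti-PD-L1
combination is synergistic in vivo:

1. **Preprocessing** — sample intersection across layers, missingness
   filtering, sample-space KNN imputation (k = 5), per-feature min–max
   scaling, top-variance feature selection (defaults 2000 mRNA / 482 miRNA
   / 2000 methylation probes / 217 proteins), concatenation into one joint
   matrix (default width 4699).
2. **Embedding** — a fully connected autoencoder (encoder
   4699 → 4000 → 1500 → 800 → 400 by default; MSE loss, Adam at 1e-3,
   batch 32, early stopping with patience 5 on a 10% validation split)
   or a deterministic PCA projection as a fast, training-free path.
3. **Consensus clustering** — K-means (K-means++ seeding) on 80% random
   subsamples, repeated many times; the consensus value of a sample pair is
   its co-clustering frequency among co-sampled replicates. Model selection
   minimizes the **PAC** (proportion of ambiguously clustered pairs,
   consensus values in (0.1, 0.9]) over candidate K; final labels come from
   average-linkage clustering of `1 − consensus`.
4. **Characterization** — per-sample signature scores (mean z over a
   nine-gene Treg signature: FOXP3, CCR8, IL2RA, TGFB1, IL10, CCL1, CCL22,
   CCL17, CXCL12), one-vs-rest signal-to-noise gene rankings, weighted-KS
   GSEA with membership-permutation NES/p/FDR, hypergeometric ORA,
   Kruskal–Wallis + Dunn + Wilcoxon group tests, and an exhaustion-marker
   panel (PDCD1, CTLA4, LAG3, TIGIT, TOX, ENTPD1).
5. **Selection** — a multi-criteria rank matrix (enriched Treg-related term
   counts, pathway NES, Treg-set NES, Treg abundance, immune score) names
   the most Treg-enriched cluster by majority of rank-1 finishes with a
   deterministic tie cascade.
6. **Efficacy** — caliper volume `V = L·W²/2`, tumor growth inhibition
   `TGI = 100·(1 − ΔT/ΔC)` (delta method; ratio method available),
   baseline-normalized AUC ratios, Highest-Single-Agent excess, Bliss
   independence (`expected = f_A + f_B − f_A·f_B`, exceedance
   `f_AB − expected`), 2×2 factorial ANOVA, and a block-randomization
   check.

A synthetic multi-omics generator with planted cluster and Treg-signature
structure (plus a tumor-growth simulator with known arm effects) provides
ground truth for every stage, so the whole pipeline is exercised without
any external download.

## Worked example

```r
library(tregstrat)

cfg <- pipeline_config(
  synthetic = synthetic_omics_config(
    n_samples = 150,
    layer_specs = default_layer_specs(n_mrna = 300, n_mirna = 100,
                                      n_meth = 200, n_protein = 60),
    cluster_sep = 3, treg_cluster = 2, treg_effect = 2, seed = 1),
  preprocess = preprocess_config(retain = c(mRNA = 150, miRNA = 50,
                                            methylation = 100, protein = 30)),
  embed_method = "pca", pca_dim = 15,
  consensus = consensus_config(k_range = 3:6, n_reps = 100, seed = 1),
  seed = 42)

res <- run_pipeline(cfg)
round(res$consensus$pac_by_k, 4)
#>      3      4      5      6
#> 0.2386 0.2475 0.3016 0.3153
adjusted_rand_index(res$consensus$labels, res$synthetic$truth$labels)
#> [1] 1
print(res$select)
#> <selection_report> cluster 2 selected: rank-1 on 5/5 criteria
#>   (go_terms->2; kegg_nes->2; gsea_nes->2; treg_fraction->2; immune_score->2)
print(res$efficacy$report)
#> <synergy_report> day 14 (delta TGI)
#>   TGI %: mono_a 5.3, mono_b 13.6, combo 39.9 (dTGI 26.4 pp)
#>   Bliss expected 0.182, exceedance 0.218; HSA excess 471.6 mm3
#>   ANOVA interaction p = 0.0619
```

PAC is lowest at the planted K = 3, the recovered labels match the planted
partition exactly (adjusted Rand index 1), and the selection framework
names the spiked cluster on all five criteria. The simulated four-arm
growth study yields a positive Bliss exceedance, i.e. the combination
inhibits growth beyond the independence expectation of its monotherapies.

The synergy arithmetic can also be applied directly to published per-arm
TGIs:

```r
syn <- synergy_indices(-17.3, 0.7, 25.4)
round(syn$bliss_exceedance, 3)
#> [1] 0.419
delta_tgi(25.4, c(-17.3, 0.7))
#> [1] 24.7
```

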