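---
title: "Methods: Treg-enriched subtype discovery and synergy analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Treg-enriched subtype discovery and synergy analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregstrat)
```

# The problem

Regulatory T cells (Tregs) accumulate in some tumors and create an
immune-rich but functionally suppressed microenvironment; such tumors tend
to resist checkpoint blockade and are candidates for Treg-directed therapy
(e.g. CCR8 antagonism combined with anti-PD-L1). `tregstrat` provides the
two analytical halves of that programme:

* an unsupervised **subtype discovery** pipeline that integrates several
  omics layers, embeds them into a low-dimensional latent space, clusters
  samples by consensus K-means, and names the most Treg-enriched cluster by
  a multi-criteria decision rule; and
* **preclinical efficacy analytics** for four-arm tumor-growth studies:
  growth inhibition, AUC burden, and Highest-Single-Agent / Bliss
  independence synergy, with a factorial ANOVA.

Everything is exercised on a synthetic generator with planted ground truth,
so each stage has an oracle.

# Preprocessing

Layers are samples-by-features matrices (`omics_layer`). The chain is
*intersect samples → filter features by missingness → KNN impute → min–max
normalize → select top-variance features → concatenate*:

* **Sample intersection** keeps the lexicographically sorted common sample
  ids — a canonical order that makes the pipeline independent of input file
  order.
* **Missingness filter**: features missing in more than `max_missing_frac`
  (default 0.2, a common QC convention; the threshold is configurable) of
  samples are dropped; the threshold is inclusive.
* **KNN imputation** (default k = 5) works in sample space: the distance
  between two samples is the Euclidean distance over features observed in
  both, rescaled by `sqrt(p/m)` for `m` shared of `p` total features (the
  `stats::dist` pairwise-complete convention). A missing entry is the mean
  of the feature over the k nearest samples that observed it. Sample-space
  imputation matches a small k relative to the number of samples; observed
  entries are never modified.
* **Min–max scaling** maps each feature to [0, 1]; constant features map to
  0 (division-by-zero guard). By default only mRNA and miRNA are scaled:
  methylation stays on native beta values and protein data are assumed
  pre-normalized; both defaults can be overridden.
* **Top-variance selection** keeps the n most variable features (defaults
  2000/482/2000/217 for mRNA/miRNA/methylation/protein), with ties broken
  by original feature order. Variance is computed after normalization for
  scaled layers, making "highly variable" comparable across features. The
  stage order filter → impute → normalize → select is a package choice; it
  is configurable only through the per-layer `normalize`/`retain` maps.
* **Concatenation** column-binds the layers with layer-prefixed feature ids
  (default joint width 2000 + 482 + 2000 + 217 = 4699) and preserves every
  retained value bit-exactly.

# Embedding

Two interchangeable paths produce the latent matrix consumed by the
clustering stage.

**Autoencoder** (`train_autoencoder()` / `encode()`): a fully connected
encoder–decoder with default hidden widths 4000/1500/800/400 (the last is
the bottleneck; the decoder mirrors the encoder), MSE reconstruction loss,
Adam at learning rate 0.001, minibatches of 32, up to 200 epochs, early
stopping with patience 5 on a 10% validation split, He (fan-in) weight
initialization. Implementation choices worth stating:

* The **output layer is linear**: inputs mix [0, 1]-scaled and unscaled
  values, so a squashing output would bias reconstruction.
* The **bottleneck layer is also linear** while every other hidden layer is
  ReLU. A rectified bottleneck can only emit nonnegative coordinates and
  therefore cannot represent a signed d-dimensional subspace at width d;
  with a linear bottleneck the network contains the optimal rank-d linear
  autoencoder as a special case, which is exactly the regime the
  subspace-recovery test checks against a truncated-SVD oracle.
* Early stopping uses strict improvement (threshold 0) of validation MSE,
  and the weights returned are always those of the best validation epoch.
* All randomness (split, init, epoch-wise shuffling) flows from one seed;
  training is bit-reproducible.
* The unstratified 90/10 split is a deliberate simplification: with
  unsupervised reconstruction there is no label to stratify on.

The network is implemented directly in base R matrix operations (forward
pass, backpropagation, Adam); at the problem sizes used here (hundreds of
samples, 10^2–10^3 features) this trains in seconds on one CPU.

**PCA** (`pca_embed()`): projection onto the top-d principal axes, with each
axis's sign fixed by making its largest-magnitude loading positive, so the
embedding is fully deterministic. It serves as a fast substitute for the AE
and as a guard: the clustering stage must recover planted structure through
*either* path, so downstream results cannot silently depend on AE
idiosyncrasies.

# Consensus clustering and PAC

For each candidate K (default 3–10), `n_reps` replicates (default 1000)
draw `floor(0.8 n)` samples without replacement and partition them with
K-means. Each replicate uses K-means++ seeding and a single start —
replicate diversity is supposed to come from the subsampling, not from
restarts. The consensus value of a pair is

```
consensus_ij = #(co-clustered & co-sampled) / #(co-sampled),
```

with never-co-sampled pairs set to 0 under a coverage warning (at 1000
replicates of 80% subsampling the probability of an uncovered pair is
negligible, but the behaviour must be defined) and the diagonal forced
to 1.

**PAC** is the fraction of upper-triangular consensus values in the
ambiguous window, by convention the open-left/closed-right interval
(0.1, 0.9]. Lower PAC = more stable clustering; `select_k()` takes the
argmin with ties resolved toward the smaller K. The candidate range starts
at 3 by default; K = 2 mostly re-derives coarse known dichotomies and a
stable 2-split would otherwise dominate the PAC criterion.

Final labels are not produced by a single K-means run: `assign_clusters()`
applies average-linkage hierarchical clustering to `1 − consensus` and cuts
at K — the standard consensus-clustering convention, deterministic given
the consensus matrix — then renumbers clusters by decreasing size.
Silhouette widths (Euclidean distance, singleton clusters scored 0) are
available for cluster-quality reporting via `silhouette_score()`.

# Characterization

* **Signature scores** (`signature_score()`): default `mean_z` — genes are
  z-scored across samples (constant genes score 0) and a sample's score is
  the mean z over the set's genes present in the matrix; absent genes are
  logged, not scored. The score is linear, order-invariant and easy to
  test. An `ssgsea_like` rank-weighted running-sum alternative is provided
  behind a flag. The nine-gene Treg signature (FOXP3, CCR8, IL2RA, TGFB1,
  IL10, CCL1, CCL22, CCL17, CXCL12) ships as `treg_signature()`.
* **Gene ranking** (`rank_genes()`): one-vs-rest signal-to-noise
  `(μ1 − μ0)/(σ1 + σ0)` with each group SD floored at `0.2·|μ|` and 1e-8
  (the classic GSEA convention), or a plain difference of means for
  log-scale data. Ties break lexicographically by gene id so rankings are
  deterministic.
* **GSEA** (`gsea()`): weighted Kolmogorov–Smirnov running sum; hits
  increment `|score|^weight` normalized to unit total, misses decrement
  `1/(N − Nh)`; ES is the running-sum extremum. The null permutes **set
  membership** rather than phenotype labels — cluster sizes vary and the
  same labels feed the whole pipeline, so membership permutation keeps the
  null well-defined at any cluster size; this is a documented divergence
  from phenotype-permuted NES. NES divides ES by the mean |null ES| of
  matching sign, and p is the matching-sign tail
  `(1 + #{|null| ≥ |ES|}) / (1 + #same-sign)`. FDR is Benjamini–Hochberg
  across the sets tested in one call.
* **ORA** (`ora()`): upper-tail hypergeometric p for the overlap between a
  hit list and a set within a universe, BH-adjusted per call.
* **Group tests** (`group_tests()`): tie-corrected Kruskal–Wallis, Dunn's
  pairwise z-tests on mean ranks (Bonferroni by default — the classical
  Dunn procedure; BH available) and pairwise Wilcoxon rank-sum tests. An
  all-constant input defines H = 0, p = 1 rather than erroring.
* **Exhaustion panel** (`exhaustion_panel()`): per-cluster Spearman
  correlation between the Treg score and a mean-z exhaustion score over
  PDCD1, CTLA4, LAG3, TIGIT, TOX, ENTPD1, plus per-marker cluster means;
  constant vectors yield 0 with a degeneracy flag.

Immune/stromal-style scores are `signature_score` over user-supplied gene
sets — explicitly a stand-in for reference-based deconvolution methods,
which are out of scope.

# Naming the Treg-enriched cluster

`build_selection_matrix()` ranks clusters within each criterion (rank 1 =
most Treg-like given the criterion's direction; ties share the minimum
rank). Interval-valued summaries like "0.05–0.07" are ingested as
midpoints. `select_treg_cluster()` applies the aggregation rule: winner =
most rank-1 finishes; ties fall to lower mean rank, then to the higher
Treg-set GSEA NES, then to cluster name order — a deterministic reading of
"strongest Treg-associated features across all analyses". The default
criteria assembled from a characterization are: count of gene sets passing
ORA FDR < 0.05, immune-pathway NES, Treg-signature NES, mean Treg
abundance, and mean immune score. The framework accepts any per-cluster
scalar with a direction flag, so externally computed Treg fractions can be
slotted in with provenance recorded by the caller.

# Efficacy and synergy

* Caliper volume `V = L·W²/2` (mm³), with length/width auto-swapped under a
  warning if violated.
* **TGI** at day d: delta method `100·(1 − (T_d − T_0)/(C_d − C_0))`
  (default) or ratio method `100·(1 − T_d/C_d)`; printed values in the
  literature rarely disambiguate the two, so both are implemented and every
  report records which was used. The delta method errors when the control
  arm did not grow.
* **ΔTGI** = combination TGI − best monotherapy TGI, in percentage points.
* **Normalized AUC**: per animal, trapezoidal AUC of `V(t)/V(0)` over the
  interval (default 0–14 d); the arm mean is expressed as a ratio to the
  control mean, so control = 1 and faster-growing arms exceed 1. The
  control-ratio scale was chosen because published monotherapy values
  straddle 1.
* **Synergy**: fractions `f = TGI/100` enter Bliss independence
  `expected = f_A + f_B − f_A·f_B`, `exceedance = f_AB − expected`.
  Negative fractions (growth acceleration) are legal and unclipped — they
  are required whenever a monotherapy worsens growth. HSA excess is the
  endpoint mean-volume reduction of the combination below the best single
  agent, in mm³.
* **Two-way ANOVA** on endpoint volumes with factors "drug A on" and
  "drug B on": on the balanced 2×2 design used here type I/II/III sums of
  squares coincide; `stats::aov` supplies the decomposition.
* **Randomization check**: per-arm and pooled baseline mean ± SD, flagging
  arms deviating from the pooled mean by more than one pooled SD.

# The synthetic test bed

`generate_multiomics()` plants K sample clusters shared across four layers
(counts-like mRNA/miRNA, beta-valued methylation, continuous protein).
Informative features (fraction `frac_informative`, default 0.2) receive
cluster-specific mean shifts drawn as `cluster_sep · N(0, 1)` on top of unit
noise — the simplest generative model under which consensus K-means
provably recovers the labels. One designated cluster additionally gains
`treg_effect` SD units on the Treg signature, the exhaustion markers and an
immune gene block, on the mRNA layer only (the Treg evidence is
transcriptomic; a flag mirrors it onto protein). Values are pushed into
each layer's domain by monotone maps (logistic for beta values, softplus
for nonnegative layers), missing entries are injected at an exact rate, and
everything is a pure function of the config seed. Defaults mirror the
study design the package addresses: 300 samples, K = 3, layer widths
2000/482/2000/217, Treg spike on cluster 2.

`generate_growth_study()` simulates
`V(t) = V0 · exp(rate · effect · t) · noise` with lognormal multiplicative
noise (volumes are positive and right-skewed), baseline 96.45 ± 12.93 mm³,
measurements on days 0, 2, 4, 7, 9, 11, 14, n = 5 per arm. The default arm
multipliers (control 1.0, mono-A 1.05, mono-B 1.0, combination 0.90) and
growth rate 0.21/day were chosen once to reproduce the qualitative pattern
of the motivating study — one monotherapy mildly accelerates growth, the
other is neutral, the combination inhibits, and the control reaches roughly
1.8·10³ mm³ by day 14; noise CV 0.1 is a typical caliper-measurement
spread. With `noise_cv = 0` every downstream metric has a closed form,
which the tests exploit.

What the generator does **not** emulate: batch structure, library-size
effects, count overdispersion, copy-number/mutation landscapes, realistic
gene–gene correlation, or inter-layer biological coupling beyond the shared
labels (a `layer_noise_corr` knob adds a shared noise factor, off by
default, since no canonical value exists). Passing tests therefore
demonstrate algorithmic correctness and recoverability of planted additive
structure — not performance on real cohorts.

# Problem sizes and numerical choices

The test suite and the worked examples run the pipeline at reduced scale —
layer widths of a few hundred features, 100–300 samples, 25–100 consensus
replicates, K scanned over 3–6, and a small AE (e.g. hidden 64/16) — sizes
at which the planted-structure recovery checks are already decisive while
the whole suite runs in well under a minute per scenario. Other numerical
conventions, collected:

* constant features min–max to 0; constant genes z-score to 0; constant
  vectors correlate as 0 with a flag;
* K-means replicates: K-means++ seeding, one start, 300 iterations max;
  duplicate seed centroids are jittered by 1e-8;
* PAC window (0.1, 0.9], open-left/closed-right; K ties to the smaller K;
* cluster renumbering by decreasing size; rank ties share the minimum rank;
* GSEA with all-zero hit weights falls back to equal increments; a set
  covering the whole list is an error (the miss denominator vanishes);
* seeds: the pipeline derives stage seeds as global seed + stage index,
  offset by each stage config's own seed, so one stage can be re-seeded
  without perturbing the others.

# Known limitations

* The AE is a plain fully connected autoencoder: no denoising/variational
  variants, no GPU, no architecture search.
* Membership-permutation GSEA p-values are not interchangeable with
  phenotype-permutation p-values from reference GSEA software, although the
  ES itself matches (cross-checked against an independent implementation).
* Signature scores are linear stand-ins for reference-based immune
  deconvolution; absolute "Treg fractions" from such tools can be supplied
  externally but are not computed here.
* The efficacy module analyses fixed-day endpoints and AUC; it deliberately
  excludes survival analysis, longitudinal mixed models and dose–response
  fitting.
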