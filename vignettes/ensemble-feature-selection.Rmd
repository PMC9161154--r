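---
title: "Ensemble feature selection for two-class expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblefs)
```

## The problem

Two histological subtypes of a tumor (generically, class 1 and class 0) are
profiled with RNA-seq, and the analyst wants a short, reliable list of genes
whose expression separates the classes — candidate diagnostic markers and
drug targets. Any single feature filter has blind spots: a univariate test
misses interacting genes, redundancy-minimising filters are unstable, and
instance-based weightings respond to different aspects of relevance. The
package therefore runs six independently implemented filters inside the same
repeated cross-validation, prunes correlated genes, validates every
candidate set with a random-forest classifier, measures how stable each
method's selections are, and finally aggregates the per-method selections
into a consensus key-gene table.

## Pipeline

For R repeats of stratified k-fold cross-validation (defaults R = 50,
k = 5, giving R·k ranked lists per method):

1. split the samples into k folds, stratified by class;
2. rank all genes on the k−1 training folds with each filter: Welch t,
   MDFS-1D, MDFS-2D, FCBF, ReliefF, MRMR;
3. scan each ranking from best to worst and drop genes whose absolute
   Spearman correlation with an already-kept gene exceeds 0.7 (computed on
   the training partition only);
4. fit a random forest (500 trees, √p features per split) on the top-N
   surviving genes;
5. score the held-out fold: AUC from the class-1 vote fractions
   (Mann–Whitney estimate, ties = ½) and MCC from the majority vote;
6. repeat for all folds, repeats and methods.

Per method and N, `run_pipeline()` reports the mean ± SD of AUC and MCC and
the Lustgarten adjusted stability measure (ASM) — the chance-corrected mean
pairwise overlap of the R·k top-N sets. The consensus step
(`select_key_genes()`) counts, per method, each gene's occurrences among
the R·k pruned top-N lists, keeps the N most frequent per method, unions
the six sets, attaches the log2 fold change (ratio of linear-scale class
means) and sorts by |Log2FC|.

Two conventions here were genuinely open and are worth stating. First,
occurrence counting uses the *pruned* lists, matching the pipeline order
(rank → prune → top-N); counting unpruned lists would reward whole blocks
of mutually redundant genes. Second, stratification of the folds is on by
default: with a 130/71 class imbalance, unstratified folds occasionally
produce a single-class test partition where the AUC is undefined.

## The six filters

**Welch t** — per gene, the unequal-variance two-sample t statistic with
Welch–Satterthwaite degrees of freedom; genes ranked by |t|. Genes with
zero variance in both classes score 0 with p = 1 rather than being
dropped, so rankings are length-stable across folds.

**MDFS-1D / MDFS-2D** — information-theoretic filters on discretized
expression. 1D scores each gene by its information gain IG(Y; X) in bits,
maximised over D random discretizations. 2D scores each gene i by the
conditional information gain H(Y|Xⱼ) − H(Y|Xᵢ,Xⱼ), maximised over draws
and partner genes j — this sees pairwise interactions (e.g. XOR-type
structure) that are invisible to any marginal statistic. P-values come
from the G statistic, G = 2N·ln(2)·IG, against a chi-square with
(c−1)(k−1) df (1D) or c(c−1)(k−1) df (2D). Because the score is a maximum
over D draws (and partners in 2D), the raw chi-square p is
anti-conservative; we apply a Šidák-style correction
1 − (1 − p)^(D·partners). The draws are positively correlated, so this is
deliberately conservative — appropriate for the error-control use, while
ranking (which the pipeline uses) is unaffected. An exact permutation null
is available (`p_method = "permutation"`), and `xor_pair_check()` uses a
200-shuffle permutation null for pair-level verdicts where it is cheap.

**FCBF** — symmetric uncertainty SU(X, Y) = 2·IG/(H(X)+H(Y)) measures both
relevance and redundancy; genes with SU > δ are scanned in decreasing SU
order and gene j is removed when an earlier kept gene i has
SU(Xᵢ, Xⱼ) ≥ SU(Xⱼ, Y). FCBF returns a self-limiting subset; the pipeline
uses its whole selected set when it is smaller than N.

**ReliefF** — on range-normalized genes, each visited instance pulls each
gene's weight down by its normalized difference to the k nearest same-class
hits and up by the difference to the k nearest other-class misses
(prior-weighted). Defaults k = 10 neighbors, all instances visited.

**MRMR** — greedy forward selection with the mutual-information-difference
criterion IG(Y; Xⱼ) − mean over selected s of IG(Xⱼ; Xₛ). The quotient
variant was not implemented; the difference (MID) form is the common
default and one had to be fixed. Selection order is the ranking and the
criterion value the score, so the score column of this one filter is not
guaranteed monotone.

### Discretization

The information-theoretic filters share one seeded
`discretization_scheme()`. Defaults: FCBF and MRMR use a single
equal-frequency cut into c = 2 bins; the MDFS filters use D = 30 random
rank-quantile cuts (uniform on the 0.15–0.85 quantile range so no bin is
degenerate) and keep the maximum-IG draw. Randomised cuts follow the idea
behind the multi-discretization design of this filter family: a single
fixed cut can sit exactly where a bimodal gene is least informative.

### Numerical conventions

IG and SU values are rounded to 1e-10 before ordering, predominance and
greedy-argmax comparisons. Mathematically tied quantities computed by
different summation orders otherwise differ by ~1e-16 and would make
tie-breaking (documented as "lower gene index first") depend on
floating-point noise. Further conventions: MCC returns 0 when a
denominator factor vanishes; ASM pairs with a zero denominator contribute
0 with a warning; a constant gene has undefined Spearman correlation and
is treated as uncorrelated during pruning; the ASM universe n is the
number of genes entering the ranking stage.

## Synthetic data generator

`generate_expression()` draws a log2 expression matrix with known ground
truth so every stage is testable offline:

- per-gene baselines ~ Uniform(2, 12) on the log2 scale — the typical
  dynamic range of log2-normalized RNA-seq — with Gaussian within-class
  noise (σ, default 1);
- *informative genes*: the class-1 mean is shifted by ±Δ (sign drawn per
  gene, recorded in the truth table);
- *correlated blocks*: a shared latent factor per block; the latent
  loading is chosen via the bivariate-normal relation
  ρ_pearson = 2·sin(π·ρ_s/6) so the empirical pairwise Spearman
  correlation lands on `block_rho`. Blocks are non-informative redundancy
  stressors by default; `blocks_informative = TRUE` attaches the latent to
  the class so a whole block carries redundant signal;
- *XOR pairs*: two latent ±1 signs per sample whose product determines the
  class up to 5% label noise; each gene is its own sign·(Δ/2) plus noise.
  Each gene is marginally independent of the class — only the 2D filter
  can see the pair;
- *batch effects*: batch b gets an additive shift `batch_shift`·(b−1) and
  a multiplicative scale `batch_scale`^(b−1), plus an independent per-gene
  jitter (SD = 10% of the shift) — the simplest structure a location/scale
  correction can remove.

The default class sizes (130 vs 71) mirror a merged two-cohort design with
unequal subtype prevalence. What the generator does *not* emulate: raw
counts and library-size normalization (inputs are already log2), heavy-tailed
or zero-inflated genes, gene-specific batch interactions beyond the jitter,
and any real co-expression topology beyond the block structure. Passing
recovery tests on this generator therefore demonstrates the machinery is
correct and well-calibrated, not that any particular biological dataset
will yield stable markers.

## Preprocessing

`log2_transform()` applies log2(x + offset). `unsupervised_filter()` keeps
genes with robust CV > 0.05 and with at least 10% of samples above a
detection threshold. The robust CV is (IQR/1.349)/|median| — IQR/1.349 being the
standard robust surrogate for the SD — with median-0 genes assigned +∞ (kept) when
their IQR is positive and 0 (dropped) otherwise. The detection threshold
is dataset-specific; `suggest_ge_threshold()` offers a knee-point heuristic
(largest second difference of the gene-retention curve) but the choice is
the analyst's. The filter is computed per dataset before merging, matching
the order of operations in a two-cohort study; computing it after merging
is a defensible alternative that would keep slightly different genes.
`merge_datasets()` intersects gene sets and concatenates samples, recording
the dataset of origin as the batch label. `batch_center()` is a per-gene,
per-batch location/scale standardization that restores each gene's global
mean and pooled SD — a naive stand-in where an empirical-Bayes correction
(e.g. ComBat) would be used on real data; pre-corrected matrices can be
supplied directly. `distribution_diagnostics()` reports per-class skewness,
Brown–Forsythe and Bartlett variance-equality p-values, and a one-sample
Kolmogorov–Smirnov normality p against a normal with estimated parameters
(the estimated-parameter bias of this KS variant is accepted and makes it
anti-conservative).

## Problem sizes used in the tests and acceptance script

The package's checks run on scaled-down analogs chosen to exercise every
mechanism at desk scale: recovery and classifier calibration on 1000 genes
x 200 samples (130/70) with 20 planted markers at Δ = 2, σ = 1, over 20
seeds; cross-validated validation at R = 5, k = 5; interaction detection
on 1000 genes x 400 samples with one XOR pair at Δ = 3, σ = 0.5;
stability comparison on 500 genes with 25 informative ρ = 0.9 blocks of 12
genes; the MDFS-2D partner search capped at 500 seeded random partners per
gene. These sizes are the package's own study conditions; the consensus
and stability behavior they demonstrate (near-perfect AUC with 20
features, FCBF's redundancy elimination lowering its ASM below the
t-test's, one survivor per correlated block after pruning) mirrors what
the ensemble design is meant to show, without claiming any external
dataset's numbers.

## Known limitations

- The 2D partner subsample (cap 500) is a seeded approximation above 501
  genes; a gene whose only informative partner is outside its sample can
  be missed in a single ranking (the CV repeats make this unlikely to
  persist across folds).
- Chi-square MDFS p-values are conservative by construction (Šidák over
  positively correlated draws); use the permutation option when exact
  error rates matter and runtime allows.
- `batch_center()` removes location/scale batch structure only.
- The KS normality test uses estimated parameters without a Lilliefors
  correction.
- Hub ranking counts all supplied edges equally; edge-type weighting is
  the caller's responsibility via the `edge_types` filter.
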