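# hgsocTyper

Two-type molecular classification of high-grade serous ovarian carcinoma
(HGSOC) from bulk RNA-seq, for translational researchers who have an
expression matrix (FPKM or TPM), and optionally allele-specific copy-number
segments, clinical tables and mutation calls, and want to reproduce the
HRR-activated vs mesenchymal dichotomy and its prognostic EMT index.

## What it computes

**EMT index.** For sample *j* and the built-in 38-gene EMT
transcription-factor panel *P* (5 core EMT-TFs — TWIST1, SNAI1, SNAI2,
ZEB1, ZEB2 — plus 33 EMT-related TFs),

EMT<sub>j</sub> = ( ∏<sub>g∈P</sub> TPM<sub>gj</sub> )<sup>1/|P|</sup>,

the geometric mean of panel TPMs, with median-split stratification into
EMT-high / EMT-low. TPM is recomputed from FPKM per sample as
FPKM<sub>gj</sub> / Σ<sub>g</sub> FPKM<sub>gj</sub> × 10⁶.

**Subtyping.** log2(TPM+1) → top variable genes → sample PCA → seeded
K-means (k = 2), plus hierarchical clustering (z-score, 1 − Pearson,
average linkage) on gene panels; the cluster with the higher mean EMT
index is labeled *mesenchymal*, the other *HRR-activated*. PC1-correlated
gene sets (|r| > 0.9) feed a local hypergeometric TF-overrepresentation
test against any GMT library with BH-FDR and top-10 reporting.

**HRD scar scores.** From allele-specific segments: LOH (> 15 Mb,
non-whole-chromosome loss of heterozygosity), NtAI (telomeric allelic
imbalance, non-centromere-crossing, > 1 Mb) and LST (breakpoints between
≥ 10 Mb neighbors after 3 Mb smoothing), their sum being the HRD score,
and its Spearman correlation with the EMT index.

**Cohort statistics and survival.** Two-sided Fisher exact
(point-probability rule), Pearson chi-square (no Yates), exact/approximate
Mann-Whitney U, one-way ANOVA, correlation, pairwise mutual-exclusivity
screening, TMB; Kaplan-Meier curves, first-crossing medians, restricted
means and the two-group log-rank test.

**Synthetic cohorts.** `generate_cohort()` draws seeded two-subtype
cohorts (log-normal expression with EMT/HRR shifts, exponential survival
with a group hazard ratio, Poisson scar events realized as valid segments,
near-disjoint driver mutations) so the whole chain is testable offline.

## Worked example

```r
library(hgsocTyper)

co  <- generate_cohort(cohort_config(seed = 3))   # 10 + 10 samples
idx <- emt_index(co$expression)                   # geometric-mean EMT index
lg  <- log_transform(co$expression)
pc  <- pca_samples(lg, select_variable_genes(lg, 1000), n_components = 2)
cl  <- assign_subtype(kmeans_two(pc$scores, emt = idx), idx)
mean(cl$subtype[names(co$subtype)] == co$subtype)
#> [1] 1

sc <- scar_table(co$segments, co$genome)
emt_hrd_correlation(sc, idx)$estimate
#> [1] -0.7477487

compare_groups(co$survival)
#>   HRR-activated: n = 10, median = 23.93219 months, rmean = 42.6
#>   mesenchymal: n = 10, median = 9.712389 months, rmean = 23.9
#>   log-rank chi-square = 2.635, p = 0.1045
```

The clustering recovers the latent subtypes exactly (agreement 1), the
HRD score anticorrelates with the EMT index (ρ ≈ −0.75: scar-rich
HRR-activated tumors score low on EMT), and the mesenchymal group has
shorter survival (median 9.7 vs 23.9 months) though a 10 + 10 cohort is
underpowered for the log-rank test at this hazard ratio — the power
analyses in the test suite use 90 + 90.

Clinical-table statistics use the same conventions as published
clinicopathologic tables, e.g.:

```r
fisher_exact_2x2(rbind(c(5, 0), c(5, 10)))   # germline BRCA1 status
#> [1] 0.03250774
chi_square_rxc(rbind(c(9, 5), c(1, 4), c(0, 1)))$p.value  # residual tumor
#> [1] 0.1392578
```

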