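---
title: "Methods: quantifying culture/disease similarity in hepatocyte transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying culture/disease similarity in hepatocyte transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepacult)
```

# The analysis problem

Primary hepatocytes deregulate thousands of genes within the first day of
culture. The workflow in this package asks a quantitative question about
those changes: *how similar are they, gene by gene and module by module, to
the changes seen in diseased or damaged liver?* The pipeline has five
analysis stages — QC, differential expression against the fresh-cell
reference, fuzzy time-course clustering into biological motifs, metagene
scoring, and concordance/quadrant statistics — plus a synthetic-data
generator that plants known structure so that every stage can be validated
end to end.

All expression values are log2 scale throughout (microarray-style
intensities after summarization; the package does not do probe-level
preprocessing or normalization).

# The synthetic world

`simulation_config()` / `simulate_timecourse()` generate a fresh-hepatocyte
reference group (day 0, condition `FH`) and culture groups (conditions ×
days). Each gene gets a baseline drawn from N(8, 2) log2 units and, if it
belongs to a planted motif, a deterministic mean fold-change trajectory;
replicate values add Gaussian noise.

Motif trajectories (peak effect `effect_size_log2`, written \(E\)):

| motif | trajectory (log2FC at day \(t\)) | shape |
|---|---|---|
| `metabolism_down_rescued` | \(-E\,a_c\,(1-e^{-t/0.4})\) | monotone down; \(a_c = 0.5\) in sandwich (`S`), 1 otherwise |
| `metabolism_down_unrescued` | \(-E\,(1-e^{-t/0.4})\) | monotone down in all conditions |
| `inflammation_transient` | \(E\,u^{3}e^{3(1-u)}\), \(u = t\) | pulse, exactly \(E\) at day 1, relaxed by day 2 |
| `inflammation_persistent` | \(E\,(1-e^{-t/0.4})\) | rises fast, stays up |
| `cellcycle` | \(E\,u^{2}e^{2(1-u)}\), \(u = t/2.5\) | delayed pulse peaking at day 2–3 |
| `cholesterol_speciesA_only` | \(E\,(1-e^{-t/0.4})\), species A only | up in one species, flat in the other |
| `background` | 0 | flat |

Default parameters and why:

* **noise_sd = 0.3** (log2). Typical residual SD between biological
  replicates of summarized expression arrays. At this noise, 4-fold planted
  effects with n = 3 replicates are detectable but not trivially so, which
  is the regime the method is meant for.
* **effect_size_log2 = 2** (4-fold peak). Well above the 2-fold call
  threshold, far below the extreme top genes real cultures show (hundreds of
  fold); chosen so that single genes are borderline and module statistics do
  the work.
* **n_replicates = 3**, timepoints 0, 1, 2, 3, 5, 7, conditions `M_C`
  (confluent monolayer), `M_S` (subconfluent monolayer), `S` (collagen
  sandwich). Three replicates per group is the usual design for this kind of
  experiment.
* **Motif sizes 200/200/150/150/60/40 of 2000 genes.** Metabolism loss is
  the largest theme, inflammation second, delayed cell-cycle and cholesterol
  modules small. Together with the fast rise times (τ = 0.4 d) this
  reproduces the qualitative day-by-day picture the method expects: the DEG
  count is maximal at day 1, later days add few genes, and sandwich totals
  stay below monolayer totals.
* The transient inflammation pulse uses exponent 3 so that it has genuinely
  relaxed (≈ 0.4 E) by day 2, separating "transient" from "persistent"
  cleanly.

**Disease conditions.** For each configured disease label with target
correlation \(\rho\), gene-level true disease fold changes are drawn from the
bivariate-normal construction
\(g = (\rho z + \sqrt{1-\rho^2}\,\varepsilon)\,s\), where \(z\) is the
standardized day-1 fold change of the anchor culture condition and \(s\) its
SD. The gene-level Pearson correlation is \(\rho\) in expectation (Spearman
is very close for bivariate normal data); replicate samples (default n = 3,
annotated `model_type = "in_vivo"`, nominal day 1) add the same Gaussian
noise.

**Two species and orthologues.** `simulate_species_pair()` simulates species
A, samples a discordant set (independent Bernoulli with
`ortholog_discordant_fraction` over effect genes), and simulates species B
with those genes' trajectories sign-flipped. The orthologue map is the
trivial one-to-one pairing gA000i–gB000i. Flips are applied at simulation
time — they must affect species-B *expression*, not just map labels, for the
flipped genes to land in the discordant quadrants downstream. The
`cholesterol_speciesA_only` motif is active in the species labelled "A";
which real species that corresponds to is a naming convention of the user's
data (in liver biology the cholesterol induction is the human-specific
response).

What the generator deliberately does **not** emulate: probe-level effects,
batch effects, missing values, heteroscedastic (intensity-dependent) noise,
correlated noise between genes, non-one-to-one orthology. A green test
establishes that the statistics recover planted structure under clean
Gaussian assumptions — not that they are robust to array artifacts.

# QC

`select_high_variance_genes()` ranks genes by sample variance (ties broken
by input order). `pca_expression()` does gene-centered PCA (no unit-variance
scaling — the variance-based gene pre-selection already treats magnitude as
meaningful) with a reproducible sign convention (largest-|loading| positive).

`flag_outlier_samples()` implements the replicate-correlation and
PCA-distance screen. Two details are worth recording because the qualitative
criterion ("more than z SDs from the group") hides them:

1. **Leave-one-out.** With replicate groups of n = 3–4, a z-score computed
   against statistics that include the candidate is bounded by
   \((n-1)/\sqrt n < 2\) and could never reach 2 or 3. Both criteria
   therefore compare the candidate against the remaining group members only.
2. **Calibration.** Leave-one-out reference sets of 2–3 values produce
   heavy-tailed z ratios. The correlation criterion additionally requires an
   absolute drop in mean replicate correlation of at least `min_cor_gap`
   (default 0.01). The PCA criterion treats the top-2-plane distance as a
   2-D chi-distributed quantity: distances are corrected for the
   leave-one-out inflation \(\sqrt{n/(n-1)}\), the noise scale is estimated
   from the pooled dataset median (replicate noise assumed homoscedastic
   across groups), and the `z_threshold` is mapped through the normal tail
   to the exact \(\chi^2_2\) quantile. Without this, "3 SDs" on a raw
   distance ratio has a ~5% per-sample false-positive rate; with it, the
   nominal normal meaning is restored. Clean simulated datasets still
   occasionally yield a stray flag (the screen is a screen); pipelines
   should drop flagged samples and verify that every group keeps ≥ 2
   replicates.

# Differential expression

Per gene and contrast (condition × day vs `FH`): Welch two-sample *t* on
log2 values. Welch rather than pooled-variance because group variances at
n = 3 are routinely unequal; a variance floor of 1e-8 guards degenerate
zero-variance groups. p-values are BH-adjusted **within each contrast**
(matching the day-by-day presentation of such analyses), and the DEG gate is

> call = up ⟺ p_adj < α **and** log2FC ≥ log2(2);  down symmetric.

"Fold change greater 2" is read inclusively (|log2FC| ≥ 1); `strict = TRUE`
switches to the strict inequality. α defaults to 0.05.

# Time-course clustering

`build_profiles()` concatenates each gene's log2 fold changes over
(condition × day) and z-scales per gene, which makes Euclidean distance
correlation-like. The day-0 anchor (fold change ≡ 0 per condition) is
prepended by default: saturating trajectories are nearly constant across
days 1–7, and without the anchor their scaled profiles would be amplified
noise — with it, they have a well-defined step shape. Constant profiles are
excluded and reported.

`fuzzy_cmeans()` is a from-scratch implementation of standard FCM
(alternating membership/center updates, Euclidean distance, fuzzifier
m = 2 by default, 10 random restarts, best final objective wins,
deterministic under `seed`). Membership updates are computed via ratios to
the row-minimum distance so small fuzzifiers cannot overflow. The objective
\(J=\sum_{ij} u_{ij}^m \lVert x_i - v_j\rVert^2\) is non-increasing across
iterations; traces are returned for inspection. `select_cluster_count()`
reports the partition coefficient and the Xie–Beni index per candidate c and
picks the Xie–Beni minimum.

`overrepresentation()` uses the one-sided hypergeometric tail with BH across
sets and a Haldane–Anscombe-corrected odds ratio. The default enrichment
universe is all genes of the matrix (per-DEG-list universes can be supplied
via `gene_set_collection()`). `assign_motifs()` labels each cluster by the
motif whose diagnostic sets reach the smallest adjusted p (ties by larger
odds ratio, unlabelled below α). `rescued_by_sandwich()` separates
sandwich-rescued from unrescued downregulated genes by the ratio of mean
|log2FC| in `S` vs `M_C`; the threshold is 0.75 — the midpoint between a
fully attenuated (50%) and an unattenuated (100%) response — because a 0.5
threshold would sit exactly on the attenuation the generator plants.

# Metagenes

A metagene score is a two-stage mean: scale per gene, average replicates
within a group, average across the set's genes. Dispersion is the SD across
genes of the group means. Two scaling modes:

* `reference_anchored` (default): \((x - \mu_{FH})/\sigma_{FH}\) per gene —
  the reference group scores exactly 0 and scores read as deviations from
  fresh cells in reference-SD units.
* `global_z`: per-gene z-score across all samples passed in the call — no
  group is privileged; matches "mean scaled value" style figures. Scaling is
  pooled across whatever samples are in the matrix (culture + disease in one
  call); per-dataset scaling can be had by calling per dataset.

Both are invariant under per-gene affine transforms of the input.

# Concordance and quadrants

`foldchange_correlation()`: Spearman rho with midranks, large-sample p; the
gene policy (union of DEGs, intersection, or all genes) is explicit in the
result. `coincidence_odds_ratio()`: over genes called up/down in **both**
comparisons (the default "shared DEG" universe; an all-genes
sign-dichotomized variant is exposed via `universe = "all"` since published
odds-ratio curves could be computed either way), the 2×2 agreement table,
OR with +0.5 correction when a cell is 0, and a two-sided Fisher exact p
computed in-package by hypergeometric enumeration (`fisher_exact_p`) —
`stats::fisher.test` is deliberately left free to serve as an independent
oracle in the tests. `odds_ratio_timecourse()` assembles per-day tables,
turning per-day failures into gaps with warnings.

`map_orthologs()` keeps one-to-one map entries only. `assign_quadrants()`
requires ≥ 2-fold deregulation in both species for any label: Q1 up/up,
Q3 down/down, Q2 A-down/B-up, Q4 A-up/B-down, everything else unassigned —
the five labels partition all pairs. Species A is the mouse-like axis of the
Q2/Q4 orientation. `quadrant_enrichment()` tests motif sets per quadrant
(universe = all pairs, BH across quadrant × set). `quadrant_metagenes()`
takes the top-k pairs per quadrant by the sum of the two per-species
|log2FC| ranks (k = 10 by default, after the "top ten deregulated genes"
convention) and scores them in both species.

# Numerical and design notes

* Determinism: every stochastic routine takes a seed; per-species and
  per-stage seeds are derived from the config seed and kept below 2^31.
* Variance floors: 1e-8 in Welch tests and metagene scaling (constant
  genes).
* Ties: high-variance selection and DEG ranking break ties by input order /
  gene ID; Spearman uses midranks.
* FCM distances are floored at 1e-16 before membership ratios; duplicated
  profiles therefore get identical membership rows.
* The BH adjustment is applied per contrast (differential), per set
  collection (enrichment) or per quadrant × set (quadrant enrichment);
  pooling across contrasts would change counts and is intentionally not
  done.
* Open choices resolved here: PCA gene selection for mixed culture/disease
  overlays uses the variance over all samples plotted together; the default
  enrichment universe is the full gene matrix; metagene scaling pools all
  samples passed in one call.

# Limitations

The generator's clean Gaussian world is a lower bound on difficulty: real
arrays have intensity-dependent noise, batch structure and annotation noise
in orthologue maps. The DEG caller is a plain Welch test — no moderated
variance (limma-style) shrinkage — so at n = 2–3 its power is conservative.
Enrichment is overrepresentation on user-supplied sets; no promoter
scanning, no running-sum GSEA, no pathway databases are bundled. Printed
quantities of the study this workflow reproduces (absolute DEG counts,
interspecies correlation coefficients, quadrant sizes) depend on its
original array data and are not reproduction targets of this package.
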