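---
title: "Single-cell qPCR subpopulation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell qPCR subpopulation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scqpcr)
```

This vignette documents the statistical model behind `scqpcr`, the
assumptions it makes, every tunable parameter that materially affects
results, what the synthetic-data generator does and does not emulate, and
the numerical conventions adopted where the method leaves room for choice.

## 1. The measurement model

A microfluidic qPCR array yields, per cell $c$ and gene $g$, a cycle
threshold $\mathrm{Ct}_{cg}$ — the PCR cycle at which fluorescence crosses
detection. Ct is a *negative* log2 scale for abundance: one cycle fewer
means roughly twice the starting transcript. A substantial fraction of
reactions produce no amplification at all; these *non-expressers* are a
mixture of true biological zeros and technical dropout, and the pipeline
deliberately does not attempt to distinguish or impute them.

### Normalization

`pooled_median_normalize()` converts Ct to relative log2 expression:

$$x_{cg} = \mathrm{clip}\!\left(\tilde m_g - \mathrm{Ct}_{cg},\; -B,\; +B\right),$$

where $\tilde m_g$ is the median Ct of gene $g$ over all *non-failed*
reactions pooled across every cell in the experiment, and $B$ (default 5)
is an absolute bound in cycle thresholds. Subtracting from the median (not
the reverse) makes lower Ct — more transcript — positive. The bound caps
representable changes at $2^B$-fold (32-fold at the default); values beyond
it carry little quantitative meaning in qPCR and would otherwise dominate
Euclidean distances. Non-expressers are excluded from $\tilde m_g$ and then
assigned to the floor $-B$, so they read as "at or below the detection
ceiling" rather than as missing.

Choices worth making explicit:

* **Pooling.** The median is pooled across both experimental groups so that
  cross-group comparisons share one reference; `pool = "group"` switches to
  within-group medians. Pooling across (rather than within) the four
  96-well plates assumes no plate-level Ct offset; the generator likewise
  simulates none.
* **Even counts.** The median of an even number of observations is the
  midpoint of the two central values (the `stats::median` convention).
* **Clipping.** Applied after centering; the interval is closed, so values
  exactly at $\pm B$ are kept, and the floor coincides with the lower clip.
* **Degenerate genes.** A gene with no successful reaction anywhere cannot
  define a median; it is kept in the matrix entirely at the floor, with a
  warning, so panel dimensions stay stable.

## 2. Subpopulation discovery

### k-means

`kmeans_partition()` minimizes the within-cluster sum of squared Euclidean
distances with Lloyd iterations. Because determinism and explicit policies
matter more here than raw speed, the loop is implemented in the package
rather than delegated:

* **Initialization**: k-means++ seeding, `n_init = 50` independent restarts,
  best WCSS kept. The seed is threaded explicitly; identical inputs and
  seeds give bit-identical models.
* **Ties**: a cell equidistant from two centroids goes to the lower cluster
  index.
* **Empty clusters**: if a cluster empties during iteration its centroid is
  re-seeded at the point currently farthest from its own centroid — the
  standard "farthest point" repair — and assignment is recomputed.
* **Non-expressers** enter clustering at their floor value $-B$; flooring
  happens before clustering, so dropout patterns *do* contribute to cluster
  geometry. This is intentional: failure to amplify is itself a repeatable
  phenotype in these arrays.

The test suite pins this implementation to an exhaustive-partition oracle
(the true WCSS minimum over all label assignments) on small problems, which
k-means++ with 50 restarts attains reliably at that scale.

### Choosing k

The partition count is chosen by maximal mean silhouette width over a
candidate range (`select_k`, default 2–8), computed with
`cluster::silhouette` on the Euclidean distance matrix. WCSS per k is also
reported so an elbow-style reading can be audited against the silhouette
choice. Two conventions:

* `select_k` uses a lighter `n_init = 10` per candidate; the final model at
  the chosen k is refit at the full 50. Selection is about ranking k, which
  is far less sensitive to restart count than the final assignment.
* A mean silhouette below 0.25 at every k flags the data as having no
  usable cluster structure (`no_structure = TRUE`); with heavy dropout this
  flag can accompany genuinely structured data (floor ties compress
  silhouettes), so it is advisory — the selected k is still returned.
  All-identical cells short-circuit to k = 1 with a warning.

Each group is clustered independently by default (mirroring a design where
subpopulation counts may differ between groups); nothing prevents fitting a
single joint model instead and splitting its assignments by group.

### Clustergram ordering

For heatmaps, `hierarchical_clustergram()` builds complete-linkage
dendrograms on Euclidean distances (merge heights are then monotone), and
`subgroup_order()` arranges clusters by a dendrogram over centroids with
cells dendrogram-ordered within each cluster — so each cluster is a
contiguous block.

## 3. Differential expression

`ks_two_sample()` computes the two-sample Kolmogorov–Smirnov statistic
$D = \sup_t |\hat F_x(t) - \hat F_y(t)|$ directly from the pooled ECDFs —
ties, in particular the mass of cells at the expression floor, are handled
by the ECDF definition with no continuity correction. The p-value uses the
asymptotic Kolmogorov series with the standard effective-sample-size
correction,

$$p = 2\sum_{j\ge1} (-1)^{j-1} e^{-2j^2\lambda^2},\qquad
\lambda = \left(\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e}\right) D,\quad
n_e = \frac{nm}{n+m}.$$

The test suite verifies calibration by simulation: at $n = m = 30$ the
uncorrected type-I error sits within $[0.03, 0.07]$ at nominal 0.05 (the
test is slightly conservative because D is discrete), and the family-wise
error over 96-gene null panels after Bonferroni stays below 0.05.

`cluster_vs_rest()` compares each cluster's cells against all remaining
cells; `group_vs_group()` splits on a two-level label. Bonferroni
multiplicity defaults to the gene panel size — one family per comparison —
with `m_scope = "genes_by_clusters"` available for the stricter
genes × clusters reading. Direction is the sign of the focal-minus-reference
median difference; for group comparisons the "first" group is the first
factor level (or C-locale order for plain labels), which makes exchanging
the two labels flip every direction while leaving D and p untouched.

Power at realistic planted conditions deserves a note: a subpopulation
occupying ~25% of one group shifts that group's marginal distribution by at
most ~0.25 in ECDF terms, so *group-level* tests of its markers are
moderately powered and fluctuate with the realized cluster size, whereas
*cluster-vs-rest* tests of the same markers are near-certain ($D$
approaching 1). The absent-subpopulation question is therefore answered
primarily by cluster matching (below), with group-level tests as support.

## 4. Cross-group cluster fate

With each group clustered independently on the same normalized panel,
`match_clusters()` aligns the two sets of clusters by an exact minimum-cost
one-to-one assignment on centroid Euclidean distances (Hungarian algorithm;
unequal cluster counts are padded with zero-cost dummies, which leaves the
real sub-assignment optimal). Matching in centroid space — rather than
re-clustering the pooled data — keeps each group's structure as its own
analysts would see it.

A matched pair is broken if its distance exceeds `max_dist`, whose default
is the 95th percentile of cell-to-centroid distances in the reference
model: "farther than essentially all cells sit from their own centroid" is
the scale-aware meaning of "no counterpart". `absence_report()` then labels
each reference cluster:

* **absent** — unmatched, or matched but with partner abundance strictly
  below `minority_floor` (default 0.02);
* **depleted** — matched with abundance ratio (B/A) below
  `depletion_ratio` (default 0.5); a partner abundance exactly at the floor
  is judged here, not as absent (strict inequality);
* **present** — otherwise.

These two thresholds are explicit stand-ins for what is usually a visual
judgement on a clustergram; both are parameters precisely because the
boundary is a scientific choice, not a mathematical one.

## 5. Immunofluorescence quantification

`quantify_image()` reproduces a standard stain-area-per-cell measurement on
RGB micrographs:

* channels are split; the blue (DAPI) channel is binarized with an
  automated, image-specific threshold — Otsu's method (`EBImage::otsu`) —
  since nuclear staining intensity varies image to image;
* the red and green stain channels use one fixed threshold for all images
  of a stain (default 0.30 on unit-scaled intensity, strictly greater
  counts as stained) so stain areas are comparable across images;
* nuclei are 8-connected components of the DAPI mask strictly larger than
  `min_nucleus_px` (default 15) pixels — the size filter suppresses
  speckle; connectivity is 8-neighbor so diagonally touching pixels join
  (the labeling is implemented in the package, as the available labeling
  routine is 4-connected);
* stain area divided by nucleus count gives area per cell; with zero
  nuclei the ratio is reported missing with a warning rather than inf/0.

Touching nuclei are *not* split (no watershed); counts are therefore
slight underestimates in dense fields, consistently in both arms of a
comparison. The 0.30 default is interpreted on unit-scaled intensity
(8-bit value 76.5/255); pass a different `stain_threshold` if a stain was
calibrated on another scale. `batch_quantify()` maps a folder of images and
summarizes mean ± SEM per experimental group.

## 6. Morphometry

Small, exact helpers: caliper tumor volume $V = 0.5\,L\,W\,H$ (cm³) and
density $D = M/V$ (g/cm³); wound closure as the per-day fraction of the
day-0 traced area, with closure the first day at or below
`closure_epsilon` (default 0 — strictly complete closure; the epsilon
exists because "closed" in practice is sometimes read at a small residual
area); and reference-gene relative expression $2^{-\Delta Ct}$ with an
optional calibrator delta for the $\Delta\Delta Ct$ convention.

## 7. The synthetic-data generator

`synthetic_spec()`/`generate_ct()` emulate the target study design so the
whole pipeline is testable without instrument data: 384 cells in four
96-well plates (two plates per group), a 96-gene panel, four latent
subpopulations with Gaussian Ct noise (sd 1.0 cycles) around
cluster-specific mean profiles, and independent per-reaction dropout.

Default generative choices, fixed once:

* **Markers**: each cluster owns a disjoint block of 8 marker genes whose
  mean Ct sits 4 cycles below baseline in that cluster — a 16-fold
  overexpression, comparable to the dynamic range a ±5 bound displays,
  and deliberately *not* saturating it.
* **Baselines**: per-gene mean Ct uniform on [18, 28], the usual
  post-preamplification range.
* **Mixing**: group A (0.30, 0.25, 0.25, 0.20); group B (0.45, 0, 0.10,
  0.45) — cluster 2 absent, cluster 3 depleted to 40% of its relative
  abundance, two clusters preserved.
* **Dropout**: 0.1 per reaction (typical failed-amplification rates in
  these arrays run ~5–15%); configurable per gene or per cluster × gene.
* **Plates**: cells fill plates sequentially in sort order; no plate/batch
  effect is simulated.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real arrays: plate- and chip-level batch effects,
doublets and sorting errors, correlated gene noise (co-regulation), dropout
that depends on expression level (real dropout is biased toward high-Ct
reactions), and non-Gaussian Ct error. Results on real data additionally
depend on panel design and sort purity, which are outside statistical
control.

`generate_image()` produces non-overlapping nucleus disks (a pixel belongs
to a disk when its squared center distance is ≤ r²: 49 px at r = 4, 13 px
at r = 2, which brackets the 15-px filter) plus stain rectangles and
optional Gaussian noise; `generate_tumor_table()` grows logistic tumors
with independent log-normal caliper and mass noise so density recovery is a
genuine simulation check.

## 8. Problem sizes and reproducibility

Simulation-backed checks in the test suite use the full 384-cell default
design: 100 seeds for cluster recovery and absent-cluster detection, 50
seeds for the structureless null, 2000 null draws for K–S type-I
calibration and 1000 panels for family-wise error — sizes at which the
binomial uncertainty of the checked proportions is well inside the asserted
margins while the whole suite stays a few-minute run. All stochastic
functions take explicit seeds and restore the caller's RNG state on exit,
so interleaving package calls does not perturb a surrounding analysis
script.

## 9. Known limitations

* The pooled-median reference makes expression *relative within the
  experiment*; values are not comparable across experiments without a
  shared reference.
* Bonferroni with K–S on floored data is conservative; genuinely small
  shifts in minor subpopulations will be missed at the strict cutoff.
  That is a property of the method being reproduced, not a defect to fix
  silently.
* Cluster matching assumes the two groups share the normalization bound
  and panel, and that centroid geometry is meaningful — it will mislabel
  clusters that split/merge between groups (a one-to-two correspondence
  has no representation in a one-to-one matching; the per-pair distances
  and abundance table are reported so such cases can be inspected).
* Silhouette-based k selection inherits silhouette's bias toward compact,
  equally sized clusters; the per-k diagnostics table is the audit trail.
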