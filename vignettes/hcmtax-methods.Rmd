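---
title: "Methods: a tree-structured taxonomy of LV morphology in HCM"
author: "hcmtax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tree-structured taxonomy of LV morphology in HCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmtax)
```

# The scientific problem

Hypertrophic cardiomyopathy (HCM) produces markedly heterogeneous patterns
of left-ventricular (LV) wall thickening — basal septal, mid-to-apical,
diffuse, mixed — that correlate imperfectly with sarcomeric genotype
(SARC-P/LP pathogenic carriers, SARC-VUS, SARC-NEG), polygenic background
and outcome. `hcmtax` implements an analysis chain for studying this
heterogeneity on a *shared template mesh*: every patient is represented by
a per-vertex wall-thickness field at end diastole (ED) and end systole
(ES), so group contrasts, unsupervised structure and risk overlays all
live in the same vertex space.

Because per-patient registry and biobank data are access-controlled, the
package ships a first-class synthetic-cohort generator whose draws carry
the statistical structure the downstream methods assume. All tests and the
acceptance script run on generated data plus the small printed cohort
counts used for summary-statistics checks.

# The synthetic cohort generator

## Template geometry

The LV epicardial atlas is surrogated by a truncated prolate spheroid
(short semi-axes 25 mm, long semi-axis 70 mm, apex at $z=0$) closed by a
flat basal cap — closed, manifold, genus 0, with outward-oriented faces.
Vertices are placed on latitude rings with per-ring counts proportional to
circumference, hitting the requested vertex budget exactly; construction
is deterministic. Regions follow a simplified 12-segment scheme:
z-tertile level (basal / mid / apical) crossed with azimuth quadrant
(septal / anterior / lateral / inferior, septal centered at azimuth 0).
This is a stand-in for an image-derived atlas, not a reproduction of one;
consequently global metrics (mass, cavity volumes via inward normal
offset) obey their physiologic invariants (EDV > ESV, mass > 0,
mass/EDV consistency) but are not expected to match clinical tables
numerically.

## Cohort model

Per-patient ED thickness at vertex $v$ is

$$ t(v) = b(v) + \beta_{\text{age}}(a_i - \bar a) + \beta_{\text{sex}}
   \mathbf{1}[\text{male}] + g_{G_i}(v) + s_i \, f_{A_i}(v) +
   \varepsilon_i(v), \qquad t(v) \ge 1\ \text{mm}, $$

with baseline $b(v)$ (9 mm, +1 mm septal), genotype effect fields
$g$ (SARC-P/LP: +3 mm basal septum, −1 mm elsewhere; VUS intermediate),
archetype fields $f$ scaled by a continuous severity $s_i \sim U(0,1)$,
and spatially smooth noise: white Gaussian per-vertex noise (default SD
1 mm) passed through 10 neighbour-averaging passes on the mesh graph — a
cheap surrogate for a Gaussian random field. ES maps add a systolic
thickening field (2.5 mm scaled by severity and a base-to-apex gradient).

The five archetypes mirror the branch phenotypes the taxonomy should
resolve: (1) mid-to-apical hypertrophy enriched for hypertension,
(2) diffuse + basal asymmetric hypertrophy enriched for outflow-tract
obstruction, (3) isolated basal hypertrophy, (4) mild diffuse hypertrophy
enriched for family history, and an undifferentiated core (zero field,
severity 0). Mixing weights default to 0.2 each.

Clinical covariates follow the registry's printed margins: genotype mix
66.0 / 9.4 / 24.6 % (NEG / VUS / P-LP), 71.1 % men, ~80 % European
ancestry, genotype-specific ages (means 62 / 61 / 49 years). The
polygenic score is genotype-conditional with a *higher* mean in
SARC-NEG (+0.3 SD vs −0.3 in P/LP), reflecting the compensatory common-
variant burden in gene-elusive disease. Survival is exponential with a
per-genotype rate (planted hazard ratio 2.66 for P/LP vs NEG) and
independent exponential censoring whose rate is calibrated so the
expected censored fraction equals the configured value (default 0.8,
matching roughly 17 % cohort mortality).

What the generator does *not* emulate: registration error, scanner and
site effects, fibrosis-thickness coupling, non-exponential hazards, and —
importantly — the heavy morphological overlap between genotypes seen in
real cohorts. With the default effect magnitudes, genotype is almost
deterministically separable from morphology, so emergent genotype-by-
branch enrichment statistics (e.g. bootstrap odds ratios) are far more
extreme than clinical values. Passing tests therefore demonstrate
correctness of the machinery and recoverability of planted truth, not
clinical effect sizes.

# Vertex-wise association maps

`vertexwiseGLM()` fits an independent OLS per vertex with the shared
design [1, covariates, predictor]; standardized coefficients are
$\hat\beta \, \mathrm{sd}(x)/\mathrm{sd}(y_v)$. Because the design is
shared, the whole map is one QR solve; the predictor's $t$ statistic is
computed on covariate-residualized predictor and responses (numerically
identical to the full-model $t$, verified against `lm()`).

Multiplicity: the default is a permutation max-T family-wise procedure in
the Freedman–Lane style — the covariate-residualized predictor is
permuted, all vertex $t$ statistics recomputed, and the corrected p value
is the rank of the observed $|t|$ in the permuted $\max|t|$ distribution
with the add-one rule $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 +
n_{\text{perm}})$, default $n_{\text{perm}} = 1000$. Benjamini–Hochberg
FDR over vertices is available as an alternative since the upstream
methodology only states that a correction was applied. Degenerate
(constant) vertices get $t = 0$, $p = 1$ by convention. Significant
regions can be outlined via `significanceContour()` (mask-boundary mesh
edges).

# The morphology taxonomy (reversed graph embedding)

`fitDDRtree()` jointly learns an orthonormal projection $W \in
\mathbb{R}^{p\times 2}$, latent coordinates $Z$, centers $Y$ and a
spanning tree $B$ by block-coordinate descent on

$$ \sum_i \lVert x_i - W z_i \rVert^2
 + \lambda \sum_{(k,k') \in B} \lVert y_k - y_{k'} \rVert^2
 + \gamma \sum_i \sum_k r_{ik}\left( \lVert z_i - y_k \rVert^2 +
   \sigma \log r_{ik} \right). $$

Each block update is an exact minimizer — $B$ a minimum spanning tree
(Prim, lexicographic tie-break), $R$ a softmax at bandwidth $\sigma$
(log-sum-exp stabilised; with small $\sigma$ the entropy-collapsed
assignment term is $-\sigma \log \sum_k e^{-d_{ik}/\sigma}$), $W$ the
orthogonal Procrustes solution of $X^\top Z$, $Z$ and $Y$ closed-form
linear solves — so the objective is provably non-increasing and this is
asserted on every fit. Defaults: $\lambda = 5$, $\sigma = 0.01$,
$\gamma = 10$, $K = \min(n/5, 50)$, `maxIter = 100`, `tol = 1e-4`;
initialisation from the first two principal components and K-means on
them. Input features are covariate-adjusted vertex maps reduced to the
principal components capturing 99 % of variance (vertex space has
$p \gg n$).

Branches: centers of tree degree ≥ 3 are branch points; maximal center
paths between branch points and leaves are branches; branch points plus
centers within radius $\rho$ (median tree edge length — the rule is
otherwise unspecified upstream) of a branch point form the
"undifferentiated" core, which takes the highest branch id. Patients
follow their highest-responsibility center, ties to the lower index. Note
that a degree-4 junction of the underlying manifold is typically
represented by two *adjacent* degree-3 centers in a spanning tree;
`branchPointClusters()` therefore counts junction clusters when the
number of distinct junctions is the quantity of interest.

Stability: `branchStability()` bootstraps patients, refits with the same
hyperparameters, and reports per-branch best-match Jaccard and adjusted
Rand. Because the embedding partitions even structureless data
deterministically and smoothly, bootstrap ARI on pure noise is moderate
(≈ 0.4), not 0; the informative contrast is structured ≫ noise.

# Projection and validation

Tree coordinates are predicted from adjusted features by two random
forests (500 trees, package defaults otherwise, fixed seeds), evaluated
by 10-fold cross-validation repeated 3 times (out-of-fold predictions
pooled per repeat, $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, averaged).
Random forests carry a bias on unbounded continuous targets, so even a
noiseless linear target cross-validates around $R^2 \approx 0.85$ at
moderate $n$; on the synthetic tree cohort (smooth coordinates, ample
signal) cross-validated $R^2$ exceeds 0.9 on both axes.

External patients are adjusted with the *development* regression
coefficients (never refit), projected, flagged as outliers when their
nearest development neighbour in coordinate space exceeds the development
99th-percentile nearest-neighbour distance, and branch-labelled by
Euclidean 1-NN (ties to the lower index; verified against a brute-force
scan).

Embedding faithfulness uses the rank-based trustworthiness

$$ M_1(k) = 1 - \frac{2}{nk(2n - 3k - 1)} \sum_i \sum_{j \in U_k(i)}
   \left( r(i,j) - k \right), $$

with $U_k(i)$ the embedding k-neighbours of $i$ absent from its original-
space k-neighbourhood and $r(i,j)$ the original-space rank; ties break by
index, $1 \le k < n/2$, reported on the grid $k \in \{5, 10, 15, 20\}$ as
a min–max range. Original-space distances are computed on the same
PCA-reduced adjusted features fed to the tree. The implementation is
checked exactly against an independent brute-force rank computation for
all $n \le 50$ instances tested.

Cohort consistency compares the within-cohort distributions of feature-to-
coordinate correlations (per feature, per axis) between development and
external cohorts with a two-sample Kolmogorov–Smirnov test; constant
features are dropped with a note.

# Phenomapping

The clinical feature table is standardized (z-scores; median imputation
for continuous, explicit "missing" level for categorical) and embedded in
2-D by a spectral neighbour embedding: a symmetrized kNN graph (default
k = 15) with locally scaled Gaussian affinities (scale = distance to the
7th neighbour), connected via minimum-spanning-tree edges, embedded by
the two non-trivial eigenvectors of the normalized graph Laplacian. The
embedding is deterministic, maps exact duplicates to identical
coordinates, and reports its own trustworthiness. K-means (25 restarts)
is run for k = 2..8 on the embedding by default (a flag allows clustering
the full standardized matrix, since either choice is defensible); the k
maximising mean silhouette wins, ties to the smaller k. When no k reaches
mean silhouette 0.5 the result carries a low-confidence flag and reports
the range minimum rather than an arbitrary winner among equally weak
splits. Enrichment per cluster uses Kruskal–Wallis (continuous) and
chi-squared or Fisher (categorical, Fisher when any expected count < 5)
with BH correction across features; constant features get p = 1.

# Risk overlays

* `overlayLogistic()`: maximum-likelihood logistic regression of a binary
  outcome on the two tree coordinates, per-axis Wald p values, and the
  fitted probability on a 100×100 grid over the coordinate bounding box.
  Complete separation (non-convergence, fitted probabilities at machine
  0/1, or |coef| > 15) triggers a small-ridge refit with a warning. The
  polygenic-score overlay binarizes at the cohort median.
* `branchOddsRatio()`: the "median odds ratio" is interpreted as the
  median of a within-branch bootstrap OR distribution (the construction
  is not described upstream), with Haldane–Anscombe 0.5 correction on
  empty cells and a permutation p for OR ≠ 1.
* `coxHazard()`: partial likelihood with Efron ties, Schoenfeld-residual
  proportional-hazards diagnostic, unadjusted or covariate-adjusted.
* `survivalSurface()`: a Cox model on the *age* time scale (entry at age
  at scan, exit at age + follow-up; left truncation makes "survival at
  median age" well defined) with the coordinates as covariates, evaluated
  per patient and on a grid.
* `kmCumulativeHazard()`: Kaplan–Meier with Greenwood variance, the
  Nelson–Aalen cumulative hazard, and the log-rank test.

# Numerical choices and tie rules

* Softmax responsibilities and the assignment objective use log-sum-exp
  with the row minimum subtracted; small $\sigma$ therefore cannot
  underflow.
* MST ties break lexicographically (lowest center index); responsibility
  ties take the lower-indexed center; 1-NN ties take the lower patient
  index; neighbour-rank ties in $M_1$ break by index.
* Percentages print at one decimal, rounded half away from zero, and
  always recompute exactly from the returned counts; genotype
  percentages use the classified subtotal while overall mortality uses
  the full cohort.
* Myocardial density is 1.05 g/mL.
* Rank-deficient adjustment designs set the offending coefficient to 0
  with a warning; rank-deficient association designs error and name the
  collinear columns.

# Problem sizes

The test suite and acceptance script run at sizes chosen to make the
statistical checks meaningful while staying desk-scale: meshes of
120–2000 vertices; cohorts of 10–5000 patients (the projection pipeline
uses n = 400 development / 60 external patients on a 500-vertex mesh);
100 replicates for family-wise-error calibration at 500 permutations;
300 replicates for Cox CI coverage (a 100-replicate coverage estimate has
SE 2.2 % and is uninformative against a 93–97 % band); 50 seeded runs for
tree-topology recovery.

# Known limitations

* The template is a geometric surrogate; absolute masses and volumes are
  not clinically scaled.
* The generator's genotype effect dominates its noise, so genotype-by-
  morphology enrichment is near-deterministic — useful for testing
  recovery, unrealistic as an effect size.
* The spectral embedding preserves neighbourhoods but, like any spectral
  method, can compress densely connected regions; trustworthiness is
  reported so this is measurable.
* Branch extraction depends on the core radius ρ; the median-edge-length
  default is a reasonable scale but other choices change how much of the
  center is labelled "undifferentiated".
* No competing risks, time-varying covariates, or continuity (the
  companion metric to trustworthiness).
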