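# hcmtax

Statistical shape analysis of the left ventricle in hypertrophic
cardiomyopathy (HCM), for researchers studying how sarcomeric genotype,
polygenic background and outcome relate to three-dimensional patterns of
wall thickening. Every patient is a per-vertex wall-thickness field on a
shared template mesh at end diastole and end systole; on that common
space the package provides:

* a **synthetic cohort generator** (template mesh + seeded cohorts with
  genotype-dependent regional effects, branch-structured morphological
  archetypes with continuous severity, genotype-conditional polygenic
  scores and genotype-dependent survival) standing in for
  access-controlled registry data;
* **vertex-wise association maps**: per-vertex OLS with age/sex/race
  adjustment, standardized β, and multiplicity correction by permutation
  max-T (Freedman–Lane) or Benjamini–Hochberg;
* a **tree-structured morphology taxonomy** by reversed graph embedding
  (DDRtree): block-coordinate descent on

  $$\sum_i \lVert x_i - W z_i\rVert^2
    + \lambda \sum_{(k,k')\in B} \lVert y_k - y_{k'}\rVert^2
    + \gamma \sum_{i,k} r_{ik}\bigl(\lVert z_i - y_k\rVert^2
    + \sigma \log r_{ik}\bigr),$$

  with spanning-tree, softmax, Procrustes and closed-form linear updates
  (objective provably non-increasing), plus branch extraction with an
  undifferentiated core and bootstrap stability (Jaccard, adjusted Rand);
* **external projection and validation**: random-forest regression of
  the two tree coordinates (repeated 10-fold CV R²), nearest-neighbour
  branch labels, rank-based trustworthiness
  $M_1(k)$, and a Kolmogorov–Smirnov cohort-consistency screen;
* **phenomapping** of clinical tables (spectral neighbour embedding,
  silhouette-optimized K-means, per-cluster enrichment tests);
* **risk overlays** on the tree: logistic probability surfaces, branch
  bootstrap odds ratios, Cox proportional hazards (Efron ties, Schoenfeld
  diagnostics), survival surfaces at median age, Kaplan–Meier and
  Nelson–Aalen curves with log-rank tests.

Central objects are Bioconductor-style S4: `ShapeCohort` (a
`SummarizedExperiment`: vertices × patients, assays `ED`/`ES`, clinical
`colData`), `TemplateMesh`, `DDRTreeFit`, `BranchAssignment`.

## Worked example

```r
library(hcmtax)

cfg <- cohortConfig(nPatients = 200, nVertices = 300, seed = 1)
coh <- simulateCohort(cfg)
coh
#> ShapeCohort: 200 patients, 300 vertices; phases: ED, ES
#>   genotype: SARC-NEG=132, SARC-VUS=14, SARC-P/LP=54

cohortSummary(clinicalTable(coh))$genotype
#>    genotype   n pct
#> 1  SARC-NEG 132  66
#> 2  SARC-VUS  14   7
#> 3 SARC-P/LP  54  27

## genotype-phenotype map: P/LP vs NEG, age/sex/race adjusted, max-T
clin  <- clinicalTable(coh)
con   <- genotypeContrast(clin, "plp_vs_neg")
assoc <- vertexwiseGLM(thicknessMaps(coh, "ED")[con$keep, ],
                       con$predictor, con$covariates)
assoc <- correctMultiplicity(assoc, "maxT", nPerm = 500, seed = 1)
#> mean standardized beta (basal septum): 0.73 | elsewhere: -0.43
#> significant vertices after max-T: 300 of 300

## morphology taxonomy on covariate-adjusted ES maps
adj <- residualizeMaps(thicknessMaps(coh, "ES"), clin)
tr  <- fitMorphologyTree(adj$residuals, seed = 1)
extractBranches(tr$fit)
#> BranchAssignment: 200 patients in 8 branches
#>   branch1=28, branch2=29, branch3=6, branch4=9, branch5=8,
#>   branch6=6, branch7=6, core=108

crossvalCoordinateR2(tr$features, treeCoordinates(tr$fit),
                     nTree = 200, seed = 1)
#> cross-validated R2: x = 0.957, y = 0.935

coxHazard(clin)
#> Cox HR (P/LP vs NEG): 3.66 [1.80, 7.43]
```

The association map shows the planted genotype signature — carriers of
pathogenic sarcomeric variants thicker in the basal septum (positive
standardized β) and thinner elsewhere (negative β) — detected at every
vertex after family-wise correction. The taxonomy separates the planted
archetypes into branches around an undifferentiated core; the tree
coordinates are predictable from the shape features with cross-validated
R² above 0.9 on both axes; and the unadjusted Cox model recovers the
planted mortality excess of P/LP carriers (true hazard ratio 2.66 inside
the interval).

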