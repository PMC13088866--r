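# scTubule

Kidney tubular epithelial cells dominate chronic kidney disease (CKD)
pathology: injured proximal tubule (PT) cells dedifferentiate, lose their
segment identity, and reprogram their metabolism from oxidative
phosphorylation (OXPHOS) toward glycolysis. `scTubule` is an R package for
dissecting this heterogeneity in single-cell RNA-seq of diseased kidney. It
is aimed at computational biologists who want a tested, fully reproducible
pipeline from a raw gene × cell count matrix to annotated cell types,
per-cell metabolic states, an injury pseudotime, and a cross-validated
cell-state classifier — together with a synthetic kidney data generator that
plants all of those signals with known ground truth, so every stage of the
pipeline is verifiable.

## What it computes

Given a sparse count matrix **X** (genes × cells):

* **QC and normalization** — per-cell `nFeature`, `nCount`, `percent.mt`,
  `percent.ribo`; threshold filtering; depth normalization to 10,000 counts
  and `log(1 + x)` transform.
* **Clustering** — variance-stabilized selection of highly variable genes,
  PCA with automatic dimensionality at the Marchenko–Pastur noise edge
  `(1 + √(p/n))²`, a shared-nearest-neighbor graph, and Leiden modularity
  clustering at resolution 0.8; UMAP for display.
* **Annotation** — cluster-level marker scores (PT segment panel: *SLC34A1,
  SLC5A2, LRP2, CUBN, ALDOB, GATM*), reference-centroid Spearman
  prediction, and one-vs-rest Wilcoxon differential expression with
  Benjamini–Hochberg correction.
* **Metabolic states** — the additive pathway score
  `s_c = Σ_{g ∈ set} x_gc` over custom glycolysis (⊇ *GPI, ENO1, HK1,
  LDHA, LDHB*) and OXPHOS/TCA (⊇ *IDH1, IDH2*) gene sets, then a
  quantile-threshold rule assigning each cell to `OXPHOS_high`, `Glyc`,
  `Dorm_Mt_high` (mitochondrial-high with both programs low), or
  `Intermediate`.
* **Trajectory** — graph-distance pseudotime over the PT compartment,
  rooted in the OXPHOS-high PT cluster and inferred from non-metabolic
  genes (dedifferentiation and damage-response expression) so that
  metabolic dynamics along the trajectory are never circular; per-cluster
  "stretched" pseudotime and binned gene dynamics.
* **Functional landscape** — per-gene importance (between-state variance of
  mean expression over the global mean) versus conservation (fraction of
  clusters with ≥ 50% detection), separating constitutive genes
  (*MALAT1*-like) from injury drivers (*ANXA1*-like).
* **Cell–cell communication** — ligand–receptor coexpression scores
  (mean ligand in sender × mean receptor in receiver) with a
  label-permutation null.
* **Classification** — a 500-tree random forest on the top variable genes,
  stratified fivefold cross-validation, macro one-vs-rest ROC/PR AUC, and
  learning curves.

## Worked example

```r
library(scTubule)
library(SingleCellExperiment)

sce <- simulateKidney(SimParams(seed = 1))   # 3000 cells, 7 renal types
sce <- computeQCMetrics(sce)
sce <- filterCells(sce)
sce <- normalizeLog(sce)
hv  <- selectHVGs(sce)
sce <- runPCA(sce, hv)
k   <- chooseKAuto(metadata(sce)$pca)        # k = 8 components
sce <- clusterCells(sce, k = k, resolution = 0.8, seed = 1)
sce <- annotateCells(sce)
sce <- addMetabolicCalls(sce)

composition(as.data.frame(colData(sce)), "cell_type")
#>   group category count fraction
#> 6   all       PT  2100     0.70
#> 1   all     Endo   240     0.08
#> 2   all      Fib   210     0.07
#> 3   all      Mac   150     0.05
#> 4   all     Peri   120     0.04
#> 5   all     Podo    90     0.03
#> 7   all       TC    90     0.03

composition(as.data.frame(colData(sce)), "metabolic_state")
#>   group     category count   fraction
#> 2   all         Glyc  1026 0.34200000
#> 4   all  OXPHOS_high  1026 0.34200000
#> 3   all Intermediate   743 0.24766667
#> 1   all Dorm_Mt_high   205 0.06833333
```

The annotated PT fraction reproduces the planted 70% composition exactly;
the four metabolic states partition the cells, with the glycolytic and
OXPHOS-high compartments defined by the 60th-percentile score thresholds
and the dormant compartment by its mitochondrial load.

The whole pipeline, including trajectory, landscape, communication and the
classifier, can be driven from one configuration:

```r
runPipeline(list(run = list(seed = 1)), outDir = "out")
```

or from a shell via `inst/scripts/sctubule.R` (verbs `simulate` and `run`).

## Package layout

* `R/` — simulator (`simulateKidney`), QC (`computeQCMetrics`,
  `filterCells`, `normalizeLog`), reduction/clustering (`selectHVGs`,
  `runPCA`, `chooseKAuto`, `clusterCells`, `embedUMAP`), annotation
  (`annotateCells`, `rankGenes`), metabolic scoring (`scorePathway`,
  `classifyState`), trajectory (`chooseRoot`, `computePseudotime`,
  `stretchPseudotime`, `geneDynamics`), landscape (`buildLandscape`),
  communication (`scoreInteractions`, `permutationTest`), classification
  (`crossValidate`, `learningCurve`), and the pipeline driver
  (`runPipeline`).
* `vignettes/methods.Rmd` — the model, its assumptions, and every numerical
  design choice.
* `inst/extdata/` — replaceable TSV catalogs: marker genes, metabolic gene
  sets, ligand–receptor pairs.
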