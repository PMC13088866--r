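---
title: "Models and methods behind scTubule"
author: "scTubule authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind scTubule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`scTubule` analyses single-cell RNA-seq of diseased kidney with a focus on
proximal tubule (PT) heterogeneity: quality control, clustering, cell-type
annotation, additive metabolic pathway scoring with a four-state
classification, injury pseudotime, a per-gene importance/conservation
landscape, ligand–receptor scoring, and a random-forest cell-state
classifier. A synthetic generator with full ground truth accompanies every
stage. This vignette records the models, the tunable parameters, and the
reasoning behind every numerically consequential design choice.

# The synthetic kidney generator

## What it emulates

`simulateKidney()` draws a sparse count matrix from a negative-binomial
model with multiplicative planted effects:

* **Composition.** Cell types are apportioned by deterministic
  largest-remainder rounding of the requested fractions, so the realized
  composition is exact (the default encodes a diseased-kidney mix with a
  70% PT majority across seven renal types). Determinism here makes
  composition recovery a sharp, not statistical, test.
* **Type identity.** Each type expresses its canonical markers (the PT
  segment panel *SLC34A1, SLC5A2, LRP2, CUBN, ALDOB, GATM*; field-standard
  sets for endothelium, fibroblasts, pericytes, podocytes, macrophages and
  T cells) plus ~25 auxiliary type-program genes, all with low baseline
  outside the type (0.3 × `nbMean`) and an `markerEffect`-fold boost inside
  (default 8). The auxiliary program matters: real cell types differ across
  hundreds of genes, and five markers alone cannot lift a 3%-abundance
  population above the PCA noise floor. A handful of the auxiliary genes
  are named after genuinely type-enriched ligands and receptors (TGFB1 in
  fibroblasts, TGFBR1/2 and MET on PT, VEGFA from podocytes, ...) so that
  communication scoring sees realistic sender/receiver structure.
* **Injury gradient.** Every PT cell carries a latent pseudotime
  t ~ U(0, 1). With m = `metabolicEffect` (default 6) and g =
  `injuryGradientStrength` (default 1.4), glycolysis genes scale by
  m^{g(t - 1/2)}, OXPHOS genes by the reciprocal, segment markers decay as
  e^{-g(t - 1/2)} (dedifferentiation), ANXA1 rises as m^{1.5 g(t - 1/2)}
  and a ten-gene damage-response module (HAVCR1, LCN2, VCAM1, SOX9, ...)
  as m^{g(t - 1/2)}. Setting g = 0 removes the gradient entirely, which is
  the null condition used to show the trajectory does not invent signal.
* **Dormant cells.** A `mitoStressFraction` (default 10%) of PT cells is
  planted as dormant/mitochondrial-high: MT- genes multiplied by m and both
  metabolic programs divided by m, keeping the residual gradient modulation.
  With the mitochondrial baseline at 15 × `nbMean` (≈ 7% of a healthy
  cell's counts), dormant cells sit at ≈ 30–40% mitochondrial fraction —
  clearly above the 25% dormancy threshold and below the 50% QC cutoff.
* **Noise.** Counts are NB(mean, size = `nbDispersion`, default 5 — a
  moderate UMI-data overdispersion) with a uniform `dropoutRate` (default
  5%) of forced zeros. All randomness flows from one seed; identical
  parameters give bit-identical output.

The default effect sizes were calibrated jointly, once, so that the three
competing planted signals coexist: state recovery needs a strong metabolic
gradient, cluster-versus-type agreement needs the PT continuum to remain a
single community at resolution 0.8, and trajectory recovery needs the
gradient to be readable. g = 1.4 with m = 6 satisfies all three with
margin across seeds.

## What it does not emulate

No batch effects, no doublets, no ambient RNA, no read-level structure
(UMIs, FASTQ), no gene–gene correlation beyond the planted programs, and a
single "sample". Passing the test suite therefore demonstrates that the
algorithms recover the signals they claim to recover under a clean
generative model — not that they are robust to the technical artifacts of
real tissue.

# Quality control and normalization

`percent.mt` and `percent.ribo` use the "MT-" and "RPS"/"RPL" symbol
prefixes. Filtering keeps a cell iff
`min_features ≤ n_feature ≤ max_features`, `percent_mt ≤ max_percent_mt`
and `n_count ≥ min_counts`; removals are attributed to the first failing
criterion in that order, and the filter is idempotent. The defaults
(200/8000 features, 50% mitochondrial, 500 counts) are conventional kidney
scRNA-seq values, deliberately explicit and overridable because no
universal thresholds exist. `percent.ribo` is reported but never used as a
filter. Normalization scales each cell to 10,000 counts and applies the
natural-log `log1p`; both constants are field convention.

# Variable genes, PCA, and the elbow

Variable-gene selection is the variance-stabilizing procedure: a loess
trend (span 0.3) of log10 variance on log10 mean of raw counts, counts
standardized by the trend-expected standard deviation and clipped at √n,
genes ranked by the variance of the clipped values (ties broken by
symbol). PCA standardizes the selected genes and takes a truncated SVD.

The "elbow" is made explicit: the selected dimensionality is the smallest
k such that the variance of component k + 1 falls below a cut, clamped to
[5, 50] (`chooseKElbow()`). For the cut, `chooseKAuto()` uses the
Marchenko–Pastur upper edge `(1 + √(p/n))²` — the largest variance a
pure-noise component of unit-scaled data attains. A cut expressed as a
fixed fraction of total variance cannot work across panel sizes: 0.5% of
the total sits inside the signal components at ~1500 genes and below the
noise bulk at ~700 genes, whereas the random-matrix edge tracks the bulk
by construction.

# Clustering

Cells are clustered on the selected components with a k-nearest-neighbor
graph (Euclidean), shared-nearest-neighbor Jaccard edge weights, and
Leiden modularity optimization at resolution 0.8 (the primary-analysis
setting), labels relabeled by decreasing size from 0. The neighborhood
default is 30: with a 70% PT continuum carrying genuine internal
(metabolic) structure, a 15-neighbor graph makes the Leiden partition
bistable — the PT blob splits into metabolic subclusters on roughly half
of simulation seeds — while 30 neighbors keep it stably coherent without
affecting the rare types (the smallest default population has 90 cells).

# Annotation and differential expression

Annotation is cluster-level: score(cluster, type) is the mean over the
type's markers of mean normalized expression in the cluster, the argmax
wins if it beats the runner-up by `minMargin` (default 0.05, on the
log-normal expression scale), ties go to the lexicographically first type,
and missing markers contribute zero. Reference-based prediction correlates
cluster centroids with reference centroids by Spearman over shared genes
(≥ 10 required).

Differential expression is a one-vs-rest two-sided Wilcoxon rank-sum per
gene with BH correction within cluster. The implementation is a vectorized
normal approximation with tie and continuity corrections that reproduces
`stats::wilcox.test(exact = FALSE)` to 10⁻⁸ (the test suite checks this
against `wilcox.test` directly on random instances). Log fold changes are
natural-log ratios of group means of normalized expression with a 10⁻⁴
stabilizer.

# Metabolic scoring and the four states

The pathway score is the plain sum of normalized expression over the set —
deliberately not a background-corrected module score, so that the additive
property (disjoint sets sum exactly) holds and the statistic stays
transparent. With G and O the `qHigh` = 0.60 quantiles of the glycolysis
and OXPHOS scores:

1. `percent_mt` > 25 and both scores below their thresholds → `Dorm_Mt_high`;
2. OXPHOS ≥ O and glycolysis < G → `OXPHOS_high`;
3. glycolysis ≥ G and OXPHOS < O → `Glyc`;
4. otherwise (including both-high) → `Intermediate`.

Quantile thresholds make the rule scale-free; the 0.60 quantile and the
25% mitochondrial threshold are package defaults (configurable), chosen as
one consistent reading of a quadrant-style state assignment in which the
states are mutually exclusive and "intermediate" is its own category.
Raising a glycolysis score can never move a cell from `Glyc` to
`OXPHOS_high` (rule 2 requires glycolysis below G).

# Trajectory

Pseudotime is the mean shortest-path distance from a root-cell ensemble
over the kNN graph (30 neighbors, Euclidean edge lengths) of the PT
compartment, rescaled to [0, 1], with one round of neighbor averaging
(diffusion smoothing, `smooth = 1`).

Three design choices deserve explanation:

* **Non-circular feature space.** `runTrajectoryPCA()` recomputes the
  components after removing the glycolysis/OXPHOS score sets and MT-
  genes. The ordering is therefore driven by dedifferentiation and
  damage-response expression, and the downstream claim — metabolic
  programs shift along the trajectory — is never circular. Concretely:
  with metabolic genes in the trajectory space, a dataset with *no*
  planted gradient still acquires a significant pseudotime–glycolysis
  correlation (the dormancy axis leaks score noise into the geometry);
  with the non-metabolic space the null correlation is indistinguishable
  from zero across seeds.
* **Root anchoring.** The root cluster is the PT cluster with the highest
  OXPHOS-high fraction (ties: larger, then lower label; clusters under 20
  cells are ineligible so splinters cannot win). Because the tubular
  compartment typically forms one cluster whose centroid sits
  mid-gradient, the root anchor is the centroid of the cluster's
  top-decile cells by segment-marker score (`markerAnchorScore()`) — the
  healthy, differentiated end — and the ensemble is all anchor cells.
  Marker genes are disjoint from the metabolic score sets, which again
  protects the null. Averaging distances over the ensemble removes the
  idiosyncrasy of any single root cell.
* **Dormant projection.** Dormant/mitochondrial-high cells are displaced
  off the injury manifold by their mitochondrial program. They are ordered
  by a nearest-neighbor projection that ignores the displacement axes
  (principal components with dormant-vs-rest standardized mean difference
  ≥ 0.5), and that ordering is then quantile-mapped onto the non-dormant
  pseudotime distribution, so dormancy itself carries no systematic
  early/late placement. Plain mean or median imputation biases dormant
  ranks toward one side of the distribution and manufactures a
  pseudotime–score association.

Stretched pseudotime min-max rescales within each cluster (singletons and
constant clusters map to 0.5, rank order preserved exactly). Gene dynamics
use 20 equal-width bins over [0, 1]; an optional five-stage quantile
discretization (`stageQuantiles()`) is provided. Disconnected graph
components are warned about and measured from their own entry points.

# Functional landscape

Neither statistic has a canonical definition, so the package fixes one and
documents it: **importance** is the population variance of per-group mean
normalized expression divided by (global mean + 0.01); **conservation** is
the fraction of clusters in which the gene is detected (count > 0) in at
least half the cluster's cells. Importance is measured across metabolic
states by default (falling back to clusters; a pseudotime-binned variant is
available via `groups =`): the conservation/variability contrast is a
statement about cell states, and when the tubular compartment is one
cluster, cluster means cannot see within-PT injury variability at all. An
alternative reading of conservation — within-state expression stability —
is noted but not implemented.

# Cell–cell communication

The interaction score is the product of mean normalized ligand expression
in the sender type and mean receptor expression in the receiver type — the
minimal coexpression statistic matching a dot-plot display (dot size: the
smaller of the two expressing fractions; color: the score). The
permutation null shuffles type labels across all cells;
p = (1 + #{permuted ≥ observed}) / (1 + nPerm), so a zero observed score
gives p = 1 by construction. A small kidney-fibrosis ligand–receptor
catalog ships as TSV; real analyses should substitute their own.

# Classification

A probability random forest (500 trees, mtry = ⌊√p⌋ — the classification
default) on normalized expression of the selected variable genes, with
stratified fivefold cross-validation. Held-out class probabilities are
pooled across folds for the headline macro one-vs-rest ROC AUC (unweighted
mean of per-class rank-statistic AUCs; a micro average is available);
per-fold AUCs capture dispersion. Learning curves hold a stratified 80/20
split fixed and subsample the training portion (3 repeats per fraction).
Classes smaller than the fold count are dropped with a warning before
training.

# Determinism

Every stochastic step (simulation, Leiden, UMAP, forests, folds,
permutations) is seeded; the pipeline routes one configuration seed to all
of them, and two runs with identical configuration produce byte-identical
tabular outputs.

# Problem sizes used by the test suite

The default study conditions are 3000 cells and ≈ 1460 genes. The test
suite runs the full default dataset once and shares it across checks;
classifier calibration uses 1500-cell simulations with 200 trees, the
determinism check uses a 1200-cell run, and module tests use toys of tens
to hundreds of cells with brute-force or closed-form oracles
(`wilcox.test`, dense summation, hand arithmetic, pROC).

# Limitations

The generator's independence assumptions (no batch structure, no
correlated background, uniform dropout) make recovery easier than on real
tissue; thresholds tuned here (QC cutoffs, `qHigh`, `mtHigh`) are starting
points, not universal constants; the trajectory assumes a single
progression axis (no branching) and the communication model ignores
multi-subunit receptor complexes and pathway-level aggregation. Cluster
nomenclature in real data ultimately needs expert review — the marker
catalog and gene sets are TSV files precisely so they can be replaced.
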