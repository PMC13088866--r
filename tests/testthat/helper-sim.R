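# Shared test utilities: small simulated objects and an independent ARI.

suppressPackageStartupMessages({
    library(SingleCellExperiment)
    library(SummarizedExperiment)
})

# adjusted Rand index, written from the pair-counting definition so cluster
# quality checks do not depend on the package under test
ariScore <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    sij <- sum(choose(tab, 2))
    e <- si * sj / choose(n, 2)
    (sij - e) / ((si + sj) / 2 - e)
}

# small normalized experiment built directly from a dense matrix
sceFromMatrix <- function(m) {
    sce <- SingleCellExperiment::SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(m, sparse = TRUE)))
    normalizeLog(sce)
}

# compact simulated dataset for module tests (cheap, still structured)
smallSim <- function(nCells = 600, seed = 42, ...) {
    sce <- simulateKidney(SimParams(nCells = nCells,
                                    nBackgroundGenes = 300,
                                    seed = seed, ...))
    sce <- computeQCMetrics(sce)
    sce <- filterCells(sce)
    normalizeLog(sce)
}

# memoised processed default dataset shared by the heavier tests
.cache <- new.env(parent = emptyenv())
processedDefault <- function() {
    if (is.null(.cache$run)) {
        sce <- simulateKidney(SimParams())
        sce <- computeQCMetrics(sce)
        sce <- filterCells(sce)
        sce <- normalizeLog(sce)
        hv <- selectHVGs(sce)
        sce <- runPCA(sce, hv, kMax = 50)
        k <- chooseKAuto(S4Vectors::metadata(sce)$pca)
        sce <- clusterCells(sce, k = k, seed = 1)
        sce <- annotateCells(sce)
        sce <- addMetabolicCalls(sce)
        .cache$run <- list(sce = sce, hv = hv, k = k)
    }
    .cache$run
}
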