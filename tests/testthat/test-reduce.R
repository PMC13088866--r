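test_that("HVG selection ranks dominant variance first and saturates", {
    set.seed(1)
    n <- 80
    m <- matrix(rpois(30 * n, 5), 30, n)
    m[1, ] <- sample(c(0, 10), n, TRUE)  # same mean, far higher variance
    dimnames(m) <- list(sprintf("G%02d", 1:30), paste0("c", 1:n))
    sce <- SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(m, sparse = TRUE)))
    hv <- selectHVGs(sce, nTop = 5)
    expect_identical(hv$gene[hv$rank == 1], "G01")
    expect_equal(sum(hv$selected), 5)
    hv_all <- selectHVGs(sce, nTop = 1000)
    expect_true(all(hv_all$selected))
    # constant matrix errors
    mc <- matrix(3, 5, 10, dimnames = list(paste0("g", 1:5),
                                           paste0("c", 1:10)))
    expect_error(selectHVGs(SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(mc, sparse = TRUE)))), "variance")
})

test_that("PCA components are orthogonal with non-increasing variance", {
    set.seed(2)
    m <- matrix(rpois(100 * 60, 3), 100, 60,
                dimnames = list(sprintf("G%03d", 1:100), paste0("c", 1:60)))
    sce <- sceFromMatrix(m)
    hv <- selectHVGs(sce, nTop = 100)
    sce <- runPCA(sce, hv, kMax = 10)
    sc <- SingleCellExperiment::reducedDim(sce, "PCA")
    expect_identical(dim(sc), c(60L, 10L))
    cross <- crossprod(sc)
    expect_true(all(abs(cross[upper.tri(cross)]) < 1e-6))
    v <- S4Vectors::metadata(sce)$pca$variance
    expect_true(all(diff(v) <= 1e-8))
    expect_error(runPCA(sce, hv, kMax = 1000), "rank")
})

test_that("rank-1 data put essentially all variance on the first component", {
    t <- seq(0, 5, length.out = 50)
    m <- outer(rep(1, 20), t) * 10 + 100   # cells on a line
    dimnames(m) <- list(paste0("g", 1:20), paste0("c", 1:50))
    sce <- SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(m, sparse = TRUE),
        logcounts = Matrix::Matrix(m, sparse = TRUE)))
    sce <- runPCA(sce, rownames(sce), kMax = 5)
    v <- S4Vectors::metadata(sce)$pca$variance
    expect_gt(v[1] / sum(v), 0.99)
})

test_that("elbow rule follows its closed form, clamps, and is scale free", {
    # geometric decay: first component under 0.1% of the total is index 4
    v <- 10 / 10^(0:5)                      # 10, 1, 0.1, ...
    k <- chooseKElbow(v, dropThreshold = 0.001, kMin = 1)
    expect_identical(k, which(v < 0.001 * sum(v))[1] - 1L)
    # flat spectrum -> no elbow -> kMax clamp
    expect_identical(chooseKElbow(rep(1, 30), kMin = 5, kMax = 20), 20L)
    # lower clamp, itself capped by the number of available components
    expect_identical(chooseKElbow(c(10, 0.0001, 0.0001), kMin = 5,
                                  kMax = 50), 3L)
    # first component below 10% of total is the 4th -> k = 3
    expect_identical(chooseKElbow(c(10, 5, 2, 1, 0.0001, 0.0001, 0.0001),
                                  dropThreshold = 0.1, kMin = 2), 3L)
    # scale invariance
    v2 <- c(8, 4, 2, 0.05, 0.01, 0.01)
    expect_identical(chooseKElbow(v2), chooseKElbow(100 * v2))
})

test_that("clustering recovers well-separated blobs and is order stable", {
    set.seed(3)
    blob <- function(center, n) sweep(matrix(rnorm(n * 4), n, 4), 2,
                                      center, "+")
    pc <- rbind(blob(c(0, 0, 0, 0), 60), blob(c(20, 20, 0, 0), 40))
    truth <- rep(c("a", "b"), c(60, 40))
    cl <- clusterCells(pc, resolution = 0.8, seed = 1)
    expect_equal(ariScore(cl, truth), 1)
    expect_identical(levels(cl), c("0", "1"))
    expect_identical(as.character(cl[1]), "0")  # largest blob labeled 0
    # single tight blob at low resolution stays one cluster
    cl1 <- clusterCells(blob(c(0, 0, 0, 0), 80), resolution = 0.1,
                        seed = 1)
    expect_identical(nlevels(cl1), 1L)
    # permutation of cell order gives the same partition
    perm <- sample(nrow(pc))
    cl2 <- clusterCells(pc[perm, ], seed = 1)
    expect_equal(ariScore(cl2, cl[perm]), 1)
    expect_error(clusterCells(pc[1:5, ], nNeighbors = 10), "fewer")
})

test_that("UMAP is seeded, finite, and separates distant blobs", {
    set.seed(4)
    pc <- rbind(matrix(rnorm(200), 50, 4),
                matrix(rnorm(200) + 20, 50, 4))
    u1 <- embedUMAP(pc, seed = 9)
    u2 <- embedUMAP(pc, seed = 9)
    expect_identical(u1, u2)
    expect_identical(dim(u1), c(100L, 2L))
    expect_true(all(is.finite(u1)))
    d <- as.matrix(dist(u1))
    intra <- mean(d[1:50, 1:50])
    inter <- mean(d[1:50, 51:100])
    expect_gt(inter, intra)
})
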