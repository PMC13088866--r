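test_that("root choice maximizes the OXPHOS-high fraction with tie rules", {
    cl <- factor(rep(c("0", "1", "2"), each = 40))
    ty <- rep(c("PT", "PT", "Endo"), each = 40)
    st <- c(rep("OXPHOS_high", 36), rep("Glyc", 4),        # cluster 0: 90%
            rep("OXPHOS_high", 4), rep("Glyc", 36),        # cluster 1: 10%
            rep("Intermediate", 40))
    expect_identical(chooseRoot(cl, ty, st), "0")
    # exact tie in fraction and size -> lower label
    st2 <- c(rep("OXPHOS_high", 20), rep("Glyc", 20),
             rep("OXPHOS_high", 20), rep("Glyc", 20),
             rep("Intermediate", 40))
    expect_identical(chooseRoot(cl, ty, st2), "0")
    expect_error(chooseRoot(cl, rep("Endo", 120), st), "PT")
    # tiny splinter clusters cannot win
    cl3 <- factor(c(rep("0", 100), rep("9", 3), rep("2", 17)))
    ty3 <- c(rep("PT", 103), rep("Endo", 17))
    st3 <- c(rep("Glyc", 100), rep("OXPHOS_high", 3),
             rep("Intermediate", 17))
    expect_identical(chooseRoot(cl3, ty3, st3), "0")
})

test_that("pseudotime is monotone along a one-dimensional chain", {
    pos <- seq(0, 30, length.out = 120)
    pc <- cbind(pos, 0)
    cl <- factor(rep("0", 120))
    pt <- computePseudotime(pc, cl, "0", nNeighbors = 5, nRoots = 1,
                            smooth = 0)
    # the root lies mid-chain (nearest the centroid): distance is monotone
    # away from it on both sides; anchored at one end it tracks position
    pt2 <- computePseudotime(pc, cl, "0", nNeighbors = 5,
                             smooth = 0, anchorScore = -pos)
    expect_gt(cor(pt2, pos, method = "spearman"), 0.99)
    # beyond the anchor region the ordering is exact
    beyond <- pos > quantile(pos, 0.15)
    expect_equal(cor(pt2[beyond], pos[beyond], method = "spearman"), 1)
    expect_equal(max(pt2), 1)
})

test_that("pseudotime is invariant to the order of cells", {
    set.seed(12)
    pc <- cbind(runif(150, 0, 20), rnorm(150))
    cl <- factor(rep("0", 150))
    sc <- -pc[, 1]
    pt <- computePseudotime(pc, cl, "0", nNeighbors = 8,
                            anchorScore = sc)
    perm <- sample(150)
    pt2 <- computePseudotime(pc[perm, ], cl, "0", nNeighbors = 8,
                             anchorScore = sc[perm])
    expect_equal(cor(pt2, pt[perm], method = "spearman"), 1)
})

test_that("disconnected components are measured from their entry points", {
    pc <- rbind(cbind(seq(0, 5, length.out = 60), 0),
                cbind(seq(100, 105, length.out = 60), 0))
    cl <- factor(rep("0", 120))
    expect_warning(pt <- computePseudotime(pc, cl, "0", nNeighbors = 5,
                                           nRoots = 1, smooth = 0),
                   "disconnected")
    expect_true(all(is.finite(pt)))
})

test_that("stretched pseudotime min-max rescales within clusters", {
    expect_equal(stretchPseudotime(c(2, 4, 6), factor(c(1, 1, 1))),
                 c(0, 0.5, 1))
    expect_equal(stretchPseudotime(5, factor("a")), 0.5)
    expect_equal(stretchPseudotime(c(3, 3, 3), factor(c("a", "a", "a"))),
                 c(0.5, 0.5, 0.5))
    # rank order preserved exactly within each cluster
    set.seed(13)
    ptv <- runif(50)
    cl <- factor(sample(c("a", "b"), 50, TRUE))
    st <- stretchPseudotime(ptv, cl)
    for (g in levels(cl))
        expect_identical(order(st[cl == g]), order(ptv[cl == g]))
    # NA pseudotime stays NA
    expect_true(is.na(stretchPseudotime(c(NA, 1, 2),
                                        factor(c("a", "a", "a")))[1]))
})

test_that("trajectory stage quantiles are balanced", {
    ptv <- c(runif(100), rep(NA, 10))
    stg <- stageQuantiles(ptv, n = 5)
    expect_true(all(is.na(stg[101:110])))
    expect_identical(sort(unique(stg[1:100])), 1:5)
    expect_true(all(abs(table(stg) - 20) <= 1))
})

test_that("binned gene dynamics: planted trends and the null gene", {
    run <- processedDefault()
    sce <- run$sce
    sce <- runTrajectoryPCA(sce, run$hv)
    root <- chooseRoot(sce$cluster, sce$cell_type, sce$metabolic_state)
    kt <- min(run$k, ncol(SingleCellExperiment::reducedDim(sce, "TRAJ")))
    pt <- suppressWarnings(computePseudotime(
        SingleCellExperiment::reducedDim(sce, "TRAJ")[, seq_len(kt)],
        sce$cluster, root, compartment = sce$cell_type == "PT",
        states = sce$metabolic_state,
        anchorScore = markerAnchorScore(sce)))
    up <- geneDynamics(sce, pt, "ANXA1", nBins = 20)
    expect_gt(up$mean[max(which(up$n > 5))], up$mean[min(which(up$n > 5))])
    down <- geneDynamics(sce, pt, "SLC34A1", nBins = 20)
    expect_lt(down$mean[max(which(down$n > 5))],
              down$mean[min(which(down$n > 5))])
    # a background gene is flat within sampling noise
    flat <- geneDynamics(sce, pt, "BG0001", nBins = 10)
    ok <- flat$n > 10
    expect_lt(diff(range(flat$mean[ok])), 0.5)
    expect_identical(nrow(flat), 10L)
    expect_error(geneDynamics(sce, pt, "NOPE"), "not present")
})
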