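test_that("marker scores equal hand-computed means on a two-cluster toy", {
    ln <- rbind(A1 = c(2, 2, 0, 0), A2 = c(4, 0, 0, 0),
                B1 = c(0, 0, 3, 3))
    colnames(ln) <- paste0("c", 1:4)
    sce <- SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(ln, sparse = TRUE),
        logcounts = Matrix::Matrix(ln, sparse = TRUE)))
    cl <- factor(c("x", "x", "y", "y"))
    catalog <- list(TA = c("A1", "A2"), TB = "B1")
    sc <- scoreClusterMarkers(sce, cl, catalog)
    expect_equal(sc["x", "TA"], mean(c(mean(c(2, 2)), mean(c(4, 0)))))
    expect_equal(sc["x", "TB"], 0)
    expect_equal(sc["y", "TB"], 3)
    # absent markers contribute zero, with a message
    expect_message(
        sc2 <- scoreClusterMarkers(sce, cl,
                                   list(TA = c("A1", "NOPE"))),
        "absent")
    expect_equal(sc2["x", "TA"], mean(c(2, 2)) / 2)
})

test_that("type assignment uses argmax, margin, and lexicographic ties", {
    sm <- rbind(c0 = c(PT = 2.0, Endo = 0.1))
    expect_identical(unname(assignTypes(sm, minMargin = 0.1)), "PT")
    tie <- rbind(c0 = c(B = 1.0, A = 1.0))
    expect_identical(unname(assignTypes(tie, minMargin = 0)), "A")
    expect_identical(unname(assignTypes(sm, minMargin = 10)), "Unassigned")
    # invariance under positive affine rescaling
    expect_identical(assignTypes(3 * sm + 5, minMargin = 0.1),
                     assignTypes(sm, minMargin = 0.1 * 3))
})

test_that("reference prediction by Spearman centroid correlation", {
    run <- processedDefault()
    sce <- run$sce
    ref <- truthCentroids(sce)
    rp <- referencePredict(sce, sce$cluster, ref)
    ann <- S4Vectors::metadata(sce)$annotation
    merged <- merge(ann, rp, by = "cluster")
    big <- merged[as.vector(table(sce$cluster)[merged$cluster]) >= 20, ]
    agree <- mean(big$marker_type == big$reference_type)
    expect_gte(agree, 6 / 7)
    # identity column gives correlation 1
    ln <- matrix(seq_len(60), 20, 3,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:3)))
    sce2 <- SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(ln, sparse = TRUE),
        logcounts = Matrix::Matrix(ln, sparse = TRUE)))
    ref2 <- cbind(T1 = ln[, 1], T2 = rev(ln[, 1]))
    rp2 <- referencePredict(sce2, factor(c("a", "a", "a")), ref2)
    expect_identical(rp2$reference_type, "T1")
    expect_equal(rp2$correlation, 1)
    # constant centroid -> Unassigned; too few shared genes -> error
    lnc <- matrix(1, 20, 3, dimnames = dimnames(ln))
    sce3 <- SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(lnc, sparse = TRUE),
        logcounts = Matrix::Matrix(lnc, sparse = TRUE)))
    expect_identical(referencePredict(sce3, factor(rep("a", 3)),
                                      ref2)$reference_type, "Unassigned")
    expect_error(referencePredict(sce2, factor(rep("a", 3)),
                                  ref2[1:5, ]), "10")
})

test_that("rank-sum p-values match stats::wilcox.test on random toys", {
    set.seed(7)
    for (i in 1:30) {
        n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
        vals <- c(rpois(n1, 3), rpois(n2, 3 + (i %% 3)))
        ln <- rbind(G = vals, H = rpois(n1 + n2, 2))
        colnames(ln) <- paste0("c", seq_len(n1 + n2))
        sce <- SingleCellExperiment(assays = list(
            counts = Matrix::Matrix(ln, sparse = TRUE),
            logcounts = Matrix::Matrix(ln, sparse = TRUE)))
        cl <- factor(rep(c("a", "b"), c(n1, n2)))
        dge <- rankGenes(sce, cl)
        for (g in c("G", "H")) {
            ours <- dge$p_value[dge$cluster == "a" & dge$gene == g]
            ref <- suppressWarnings(stats::wilcox.test(
                ln[g, cl == "a"], ln[g, cl == "b"],
                exact = FALSE, correct = TRUE))$p.value
            expect_equal(ours, ref, tolerance = 1e-8)
        }
    }
})

test_that("differential expression finds exclusive genes and respects BH", {
    set.seed(8)
    ln <- rbind(EXC = c(rpois(20, 6), rep(0, 20)),
                matrix(rpois(30 * 40, 2), 30, 40))
    rownames(ln)[-1] <- sprintf("N%02d", 1:30)
    colnames(ln) <- paste0("c", 1:40)
    sce <- SingleCellExperiment(assays = list(
        counts = Matrix::Matrix(ln, sparse = TRUE),
        logcounts = Matrix::Matrix(ln, sparse = TRUE)))
    cl <- factor(rep(c("a", "b"), each = 20))
    dge <- rankGenes(sce, cl)
    a <- dge[dge$cluster == "a", ]
    expect_identical(a$gene[1], "EXC")
    expect_lt(a$fdr[1], 0.05)
    expect_gt(a$log_fold_change[1], 0)
    # BH adjusted values are monotone in p after sorting
    expect_true(all(diff(a$fdr[order(a$p_value)]) >= -1e-12))
    # identical distributions are not significant
    nullrow <- a[a$gene == "N01", ]
    expect_gt(nullrow$p_value, 0.01)
    # undersized cluster skipped with warning
    cl2 <- factor(c(rep("a", 38), "b", "b"))
    expect_warning(rankGenes(sce, cl2, minCells = 3), "skipping")
})
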