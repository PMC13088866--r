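test_that("gene panel contains the required programs exactly once per gene", {
    params <- SimParams(nCells = 100)
    panel <- buildGenePanel(params)

    pt <- panel$gene[panel$program == "type_marker:PT"]
    expect_true(all(c("SLC34A1", "SLC5A2", "LRP2", "CUBN", "ALDOB",
                      "GATM") %in% pt))
    expect_true(all(c("GPI", "ENO1", "HK1", "LDHA", "LDHB") %in%
                    panel$gene[panel$program == "glycolysis"]))
    expect_true(all(c("IDH1", "IDH2") %in%
                    panel$gene[panel$program == "oxphos"]))
    expect_gte(sum(grepl("^MT-", panel$gene)), 5)
    expect_gte(sum(grepl("^RP[SL]", panel$gene)), 5)
    expect_identical(panel$program[panel$gene == "MALAT1"], "conserved")
    expect_identical(panel$program[panel$gene == "ANXA1"],
                     "injury_variable")
    for (ty in names(params@typeProportions))
        expect_true(any(panel$program == paste0("type_marker:", ty)))
    expect_equal(sum(panel$program == "background"),
                 params@nBackgroundGenes)
    # one program per gene, no duplicates
    expect_false(anyDuplicated(panel$gene) > 0)

    p0 <- buildGenePanel(SimParams(nCells = 100, nBackgroundGenes = 0))
    expect_false(any(p0$program == "background"))
    expect_equal(nrow(p0), nrow(panel) - params@nBackgroundGenes)
})

test_that("largest-remainder apportionment is exact and deterministic", {
    props <- c(PT = 0.70, Endo = 0.08, Fib = 0.07, Mac = 0.05,
               Peri = 0.04, Podo = 0.03, TC = 0.03)
    n <- largestRemainder(3000, props)
    expect_identical(sum(n), 3000L)
    expect_identical(unname(n["PT"]), 2100L)
    # a case with remainders
    n2 <- largestRemainder(10, c(a = 1 / 3, b = 1 / 3, c = 1 / 3))
    expect_identical(sum(n2), 10L)
    expect_identical(unname(n2), c(4L, 3L, 3L))  # ties broken by name
})

test_that("simulation is reproducible and composition exact", {
    sp <- SimParams(nCells = 400, nBackgroundGenes = 100, seed = 7)
    a <- simulateKidney(sp)
    b <- simulateKidney(sp)
    expect_identical(as.matrix(assay(a, "counts")),
                     as.matrix(assay(b, "counts")))
    expect_identical(a$true_state, b$true_state)
    expect_identical(as.vector(table(a$true_type)[names(sort(
        table(a$true_type)))]),
        as.vector(largestRemainder(400, sp@typeProportions)[names(sort(
            table(a$true_type)))]))
    # pseudotime defined exactly on PT cells
    expect_true(all(!is.na(a$true_pseudotime[a$true_type == "PT"])))
    expect_true(all(is.na(a$true_pseudotime[a$true_type != "PT"])))
    expect_error(simulateKidney(SimParams(nCells = 3)), "smaller")
})

test_that("neutral configuration reproduces the baseline NB means", {
    sp <- SimParams(nCells = 3000, nBackgroundGenes = 200,
                    markerEffect = 1, metabolicEffect = 1,
                    injuryGradientStrength = 0, mitoStressFraction = 0,
                    dropoutRate = 0, nbDispersion = 1e6, seed = 3)
    sce <- simulateKidney(sp)
    m <- Matrix::rowMeans(assay(sce, "counts"))
    base <- rowData(sce)$base_mean
    se <- sqrt(base / ncol(sce))   # ~Poisson at huge dispersion
    expect_true(all(abs(m - base) < 3.2 * se))
})

test_that("planted marker signal separates every type", {
    sce <- simulateKidney(SimParams(nCells = 700, nBackgroundGenes = 100,
                                    markerEffect = 8, seed = 11))
    counts <- as.matrix(assay(sce, "counts"))
    prog <- rowData(sce)$program
    for (ty in unique(sce$true_type)) {
        sel <- prog == paste0("type_marker:", ty)
        own <- mean(counts[sel, sce$true_type == ty])
        other <- mean(counts[sel, sce$true_type != ty])
        expect_gt(own, other)
    }
})

test_that("glycolysis counts rise monotonely along planted pseudotime", {
    sce <- simulateKidney(SimParams(seed = 5))
    pt_cells <- sce$true_type == "PT"
    glyc <- Matrix::colSums(
        assay(sce, "counts")[rowData(sce)$program == "glycolysis", ])
    ct <- cor.test(sce$true_pseudotime[pt_cells], glyc[pt_cells],
                   method = "spearman", exact = FALSE)
    expect_gt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.01)
})

test_that("invalid parameter combinations are rejected", {
    expect_error(SimParams(typeProportions = c(PT = 0.5, Endo = 0.4)),
                 "sum to 1")
    expect_error(SimParams(markerEffect = 0.5), ">= 1")
    expect_error(SimParams(dropoutRate = 1), "dropout")
    expect_error(SimParams(nbDispersion = 0), "positive")
})
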